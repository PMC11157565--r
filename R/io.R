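detect_delim <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl("\t", first)) "\t" else ","
}

#' Read a delimited feature table
#'
#' Reads a CSV or TSV table (delimiter auto-detected from the first
#' line) into the canonical samples-as-rows layout. Supplement-style
#' tables that store one feature per row are handled with
#' `orientation = "features_as_rows"` and transposed on load. A leading
#' non-numeric column is taken as sample (or feature) identifiers. Rows
#' containing any missing value are dropped with a message stating the
#' count; a non-numeric cell in the data body is an error naming the
#' offending row and column.
#'
#' @param path Path to a delimited text file with a header row.
#' @param orientation `"samples_as_rows"` (default) or
#'   `"features_as_rows"`.
#' @param target_columns Optional character vector of column names to
#'   split out as targets.
#'
#' @return A list with `features` (tibble: `sample_id` plus numeric
#'   feature columns), `targets` (tibble of the named target columns, or
#'   `NULL`), and `n_dropped` (rows removed for missingness).
#' @export
read_feature_table <- function(path,
                               orientation = c("samples_as_rows",
                                               "features_as_rows"),
                               target_columns = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  delim <- detect_delim(path)
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                           progress = FALSE, show_col_types = FALSE)

  id_col <- NULL
  if (ncol(raw) > 1 && !is.numeric(raw[[1]]) &&
      suppressWarnings(anyNA(as.numeric(raw[[1]][!is.na(raw[[1]])])))) {
    id_col <- raw[[1]]
    raw <- raw[-1]
  }

  # every remaining cell must be numeric; name the first offender
  for (j in seq_along(raw)) {
    col <- raw[[j]]
    if (!is.numeric(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(!is.na(col) & is.na(num))
      if (length(bad) > 0) {
        abort(paste0("non-numeric value ", encodeString(col[bad[1]], quote = "\""),
                     " at row ", bad[1], ", column ", names(raw)[j], "."))
      }
      raw[[j]] <- num
    }
  }

  if (orientation == "features_as_rows") {
    feature_names <- if (!is.null(id_col)) id_col else
      paste0("feature_", seq_len(nrow(raw)))
    sample_ids <- names(raw)
    mat <- t(as.matrix(raw))
    colnames(mat) <- feature_names
    tbl <- tibble::as_tibble(mat)
  } else {
    sample_ids <- if (!is.null(id_col)) id_col else
      paste0("sample_", seq_len(nrow(raw)))
    tbl <- raw
  }

  complete <- !apply(is.na(as.matrix(tbl)), 1, any)
  n_dropped <- sum(!complete)
  if (n_dropped > 0) {
    inform(paste0("dropped ", n_dropped, " row(s) with missing values."))
    tbl <- tbl[complete, , drop = FALSE]
    sample_ids <- sample_ids[complete]
  }
  if (nrow(tbl) < 2) abort("fewer than 2 complete samples after loading.")

  targets <- NULL
  if (!is.null(target_columns) && length(target_columns) > 0) {
    missing <- setdiff(target_columns, names(tbl))
    if (length(missing) > 0) {
      abort(paste0("target column(s) not found: ",
                   paste(missing, collapse = ", ")))
    }
    targets <- tbl[target_columns]
    for (nm in target_columns) {
      if (var(targets[[nm]]) == 0) {
        abort(paste0("target column `", nm, "` has zero variance."))
      }
    }
    # a targets-only file legitimately leaves zero feature columns
    tbl <- tbl[setdiff(names(tbl), target_columns)]
  }

  list(
    features = dplyr::bind_cols(tibble::tibble(sample_id = sample_ids), tbl),
    targets = targets,
    n_dropped = n_dropped
  )
}

#' Write a feature table to CSV
#'
#' Inverse of [read_feature_table()] for the samples-as-rows layout;
#' round trips are lossless for finite doubles.
#'
#' @param data Data frame (a `sample_id` column is written first if
#'   present).
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_feature_table <- function(data, path) {
  readr::write_csv(data, path)
  invisible(path)
}

#' Write a results bundle to a directory
#'
#' Serializes a fitted [mcmopso()] result as plain-text artifacts:
#' \describe{
#'   \item{candidate_trace.csv}{every prefix size evaluated by the
#'     forward search with its CV RMSE.}
#'   \item{candidate_features.csv}{the chosen candidate subset in rank
#'     order.}
#'   \item{pareto_front.csv}{one row per front member: `n_features`,
#'     `rmse`, `r2`, `mae`, and `feature_names` (semicolon-joined).}
#'   \item{manifest.json}{the full run configuration (including the
#'     seed), sufficient to rerun and reproduce the front exactly.}
#' }
#' Output is deterministic: rerunning with the same seed and
#' configuration writes byte-identical CSVs.
#'
#' @param result An `mcmopso_result`.
#' @param out_dir Output directory (created if needed).
#' @return Tibble manifest of the written files (`file`, `path`),
#'   invisibly.
#' @export
write_results <- function(result, out_dir) {
  if (!inherits(result, "mcmopso_result")) {
    abort("`result` must be an `mcmopso_result`.")
  }
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE)
  if (!ok || file.access(out_dir, 2) != 0) {
    abort(paste0("cannot write to directory: ", out_dir))
  }
  paths <- c(
    candidate_trace = file.path(out_dir, "candidate_trace.csv"),
    candidate_features = file.path(out_dir, "candidate_features.csv"),
    pareto_front = file.path(out_dir, "pareto_front.csv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  readr::write_csv(result$candidate$trace, paths[["candidate_trace"]])
  readr::write_csv(
    tibble::tibble(rank = seq_along(result$candidate$features),
                   feature = result$candidate$features),
    paths[["candidate_features"]]
  )
  front_flat <- result$front |>
    dplyr::mutate(feature_names = purrr::map_chr(.data$features, paste,
                                                 collapse = ";")) |>
    dplyr::select("n_features", "rmse", "r2", "mae", "feature_names")
  readr::write_csv(front_flat, paths[["pareto_front"]])
  jsonlite::write_json(
    list(tool = "swarmselect",
         version = as.character(utils::packageVersion("swarmselect")),
         target = result$target,
         n_features_total = result$n_features_total,
         config = result$config),
    paths[["manifest"]],
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(tibble::tibble(file = names(paths), path = unname(paths)))
}

#' Reload a run manifest
#'
#' Reads the `manifest.json` written by [write_results()]; the embedded
#' configuration (with its seed) is everything needed to rerun
#' [mcmopso()] and reproduce the front.
#'
#' @param path Path to a manifest JSON file.
#' @return The manifest as a list; `$config` holds the run
#'   configuration.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  jsonlite::read_json(path, simplifyVector = TRUE)
}
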
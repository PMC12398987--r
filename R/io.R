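# Plain-text persistence for case collections: a CSV with one row per case
# (case_id, split, f01..f16, p01..p16) plus a JSON sidecar carrying the
# generator configuration, seed and the vocabulary index tables, so a file
# is self-describing and encodings can be cross-checked on read.

sidecar_path <- function(path) {
  if (grepl("\\.csv$", path)) sub("\\.csv$", ".meta.json", path)
  else paste0(path, ".meta.json")
}

#' Write a case collection to disk
#'
#' Writes the documented CSV dialect (`case_id,split,f01..f16,p01..p16`)
#' and a `*.meta.json` sidecar holding the generator configuration and the
#' vocabulary index tables.
#'
#' @param collection A `case_collection`.
#' @param path Output CSV path.
#' @return The CSV path, invisibly.
#' @export
write_collection <- function(collection, path) {
  stopifnot(inherits(collection, "case_collection"))
  df <- data.frame(case_id = collection$case_id, split = collection$split,
                   stringsAsFactors = FALSE)
  fm <- as.data.frame(collection$findings, stringsAsFactors = FALSE)
  names(fm) <- sprintf("f%02d", seq_len(N_TEETH))
  pm <- as.data.frame(collection$plans, stringsAsFactors = FALSE)
  names(pm) <- sprintf("p%02d", seq_len(N_TEETH))
  utils::write.csv(cbind(df, fm, pm), path, row.names = FALSE, quote = FALSE)
  meta <- list(format = "dentplan-cases",
               version = as.character(utils::packageVersion("dentplan")),
               n_cases = n_cases(collection),
               config = unclass(collection$config),
               finding_index = as.list(stats::setNames(
                 seq_along(FINDING_SYMBOLS) - 1L, FINDING_SYMBOLS)),
               plan_index = as.list(stats::setNames(
                 seq_along(PLAN_SYMBOLS) - 1L, PLAN_SYMBOLS)))
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Read a case collection from disk
#'
#' Reads a CSV written by [write_collection()] and its sidecar, validating
#' the column layout, every symbol, and -- when a sidecar is present --
#' that the embedded vocabulary index tables match the package's.
#'
#' @param path CSV path.
#' @return A `case_collection`.
#' @export
read_collection <- function(path) {
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE)
  want <- c("case_id", "split",
            sprintf("f%02d", seq_len(N_TEETH)),
            sprintf("p%02d", seq_len(N_TEETH)))
  if (!identical(names(df), want))
    stop(sprintf("malformed case file: expected %d columns (%s...), found %d",
                 length(want), paste(want[1:4], collapse = ","), ncol(df)),
         call. = FALSE)
  fmat <- as.matrix(df[, sprintf("f%02d", seq_len(N_TEETH))])
  pmat <- as.matrix(df[, sprintf("p%02d", seq_len(N_TEETH))])
  dimnames(fmat) <- dimnames(pmat) <- NULL
  bad <- which(!(fmat %in% FINDING_SYMBOLS))
  if (length(bad)) {
    row <- (bad[1L] - 1L) %% nrow(fmat) + 1L
    stop(sprintf("unknown finding symbol '%s' on data line %d",
                 fmat[bad[1L]], row), call. = FALSE)
  }
  bad <- which(!(pmat %in% PLAN_SYMBOLS))
  if (length(bad)) {
    row <- (bad[1L] - 1L) %% nrow(pmat) + 1L
    stop(sprintf("unknown plan symbol '%s' on data line %d",
                 pmat[bad[1L]], row), call. = FALSE)
  }
  if (!all(df$split %in% c("trainpool", "test")))
    stop("split column must contain only 'trainpool' or 'test'",
         call. = FALSE)

  config <- NULL
  meta_file <- sidecar_path(path)
  if (file.exists(meta_file)) {
    meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
    fi <- unlist(meta$finding_index)
    pi <- unlist(meta$plan_index)
    if (!identical(names(fi), FINDING_SYMBOLS) ||
        !identical(unname(as.integer(fi)), seq_along(FINDING_SYMBOLS) - 1L) ||
        !identical(names(pi), PLAN_SYMBOLS) ||
        !identical(unname(as.integer(pi)), seq_along(PLAN_SYMBOLS) - 1L))
      stop("vocabulary index tables in sidecar do not match this package",
           call. = FALSE)
    if (!is.null(meta$config)) {
      cfg <- meta$config
      int_fields <- c("n_total", "n_test", "seed", "max_missing",
                      "max_rdp_teeth", "max_bridges", "max_pontics")
      for (f in int_fields) cfg[[f]] <- as.integer(cfg[[f]])
      config <- structure(cfg, class = "generator_config")
    }
  }
  structure(list(findings = fmat, plans = pmat,
                 case_id = as.integer(df$case_id), split = df$split,
                 config = config),
            class = "case_collection")
}
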
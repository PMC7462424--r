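#' Write / read a square matrix as TSV with region ids
#'
#' Matrices are stored as tab-separated text with region ids as both the
#' header row and the first column. On read the matrix must be square,
#' free of non-finite entries, and symmetric within `tol` (it is then
#' exactly symmetrized).
#'
#' @param m numeric square matrix; unnamed dimensions get ids `R1..Rn`.
#' @param path file path.
#' @return `write_matrix` invisibly returns `path`; `read_matrix` returns
#'   the matrix with region-id dimnames.
#' @export
write_matrix <- function(m, path) {
  m <- as.matrix(m)
  if (is.null(rownames(m))) rownames(m) <- paste0("R", seq_len(nrow(m)))
  colnames(m) <- rownames(m)
  df <- data.frame(region = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix
#' @param tol symmetry tolerance on read.
#' @export
read_matrix <- function(path, tol = 1e-8) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (nrow(m) != ncol(m)) {
    stop("matrix in ", path, " is not square: ", nrow(m), " x ", ncol(m))
  }
  if (any(!is.finite(m))) {
    stop("matrix in ", path, " contains non-finite entries")
  }
  if (max(abs(m - t(m))) > tol) {
    stop("matrix in ", path, " is asymmetric beyond tolerance ", tol)
  }
  m <- (m + t(m)) / 2
  dimnames(m) <- list(ids, ids)
  m
}

#' Read a set of subject matrices with consistent region ids
#'
#' @param paths character vector of TSV matrix paths.
#' @param tol symmetry tolerance.
#' @return list of matrices; errors list the mismatching ids if region
#'   ids differ across files.
#' @export
read_matrix_set <- function(paths, tol = 1e-8) {
  ms <- lapply(paths, read_matrix, tol = tol)
  ids <- rownames(ms[[1]])
  for (i in seq_along(ms)[-1]) {
    if (!identical(rownames(ms[[i]]), ids)) {
      stop("region-id mismatch between ", paths[1], " and ", paths[i],
           ": ", paste(setdiff(union(ids, rownames(ms[[i]])),
                               intersect(ids, rownames(ms[[i]]))),
                       collapse = ", "))
    }
  }
  ms
}

#' Write / read a trial design as TSV
#'
#' Columns: index, condition, numerosity, onset_s, duration_s, isi_ms.
#' Design-level parameters (tr, n_volumes, response duration, run
#' constraint, configured ISI/numerosity sets) travel in `#`-prefixed
#' header comments so the round trip is lossless.
#'
#' @param design a `trial_design`.
#' @param path file path.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "trial_design"))
  hdr <- c(
    paste0("# tr=", design$tr),
    paste0("# n_volumes=", design$n_volumes),
    paste0("# response_dur=", design$response_dur),
    paste0("# max_run=", design$max_run),
    paste0("# isi_set=", paste(design$isi_set, collapse = ",")),
    paste0("# numerosities=", paste(design$numerosities, collapse = ","))
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.table(design$trials, con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  field <- function(key) sub(paste0("^# ", key, "="), "",
                             grep(paste0("^# ", key, "="), hdr, value = TRUE))
  trials <- read.delim(text = lines[!grepl("^#", lines)],
                       stringsAsFactors = FALSE)
  structure(
    list(trials = trials,
         tr = as.numeric(field("tr")),
         n_volumes = as.integer(field("n_volumes")),
         response_dur = as.numeric(field("response_dur")),
         max_run = as.integer(field("max_run")),
         isi_set = as.numeric(strsplit(field("isi_set"), ",")[[1]]),
         numerosities = as.numeric(strsplit(field("numerosities"), ",")[[1]])),
    class = "trial_design"
  )
}

#' Write / read a partition as two-column TSV
#'
#' @param partition community label vector.
#' @param path file path.
#' @export
write_partition <- function(partition, path) {
  df <- data.frame(region_id = seq_along(partition),
                   community = as.integer(partition))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_partition
#' @export
read_partition <- function(path) {
  df <- read.delim(path)
  as.integer(df$community[order(df$region_id)])
}
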
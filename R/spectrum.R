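#' Construct an allele frequency spectrum
#'
#' An AFS is a P-dimensional array of SNP counts (or expectations) indexed
#' by joint derived-allele frequency: dimension i has `sample_sizes[i] + 1`
#' cells ordered `0, 1, ..., 2n_i` derived copies, where `sample_sizes[i]`
#' is the number of chromosomes sampled from population i.  The two
#' absorbing corner cells (all-ancestral and all-derived) carry no
#' polymorphism information and are always masked.
#'
#' @param entries numeric vector (one population) or matrix (two
#'   populations) of non-negative per-cell values.
#' @param sample_sizes integer vector of chromosome counts `2n_i`; dimension
#'   i of `entries` must have length `sample_sizes[i] + 1`.
#' @param kind `"expected"` (real-valued model spectrum) or `"observed"`
#'   (integer counts).
#' @param mask optional logical array of the same shape, `TRUE` = excluded
#'   cell.  The corners are masked regardless.
#' @param pop_labels optional character vector of population names.
#' @return An object of class `"afs"`.
#' @examples
#' afs(c(0, 3, 2, 1, 0), sample_sizes = 4, kind = "observed")
#' @export
afs <- function(entries, sample_sizes, kind = c("expected", "observed"),
                mask = NULL, pop_labels = NULL) {
  kind <- match.arg(kind)
  sample_sizes <- as.integer(sample_sizes)
  if (any(sample_sizes < 1)) stop("sample sizes must be positive chromosome counts")
  entries <- if (length(sample_sizes) == 1L) as.numeric(entries) else as.matrix(entries)
  dims <- if (is.matrix(entries)) dim(entries) else length(entries)
  if (length(dims) != length(sample_sizes) || any(dims != sample_sizes + 1L))
    stop("entries shape ", paste(dims, collapse = "x"),
         " inconsistent with sample sizes ", paste(sample_sizes, collapse = ","),
         " (need 2n_i + 1 cells per dimension)")
  if (is.null(mask)) {
    mask <- array(FALSE, dim = if (is.matrix(entries)) dim(entries) else length(entries))
  } else {
    mask <- if (is.matrix(entries)) as.matrix(mask) else as.logical(mask)
    md <- if (is.matrix(entries)) dim(mask) else length(mask)
    if (any(md != dims)) stop("mask shape does not match entries")
  }
  mask <- .mask_corners(mask)
  if (any(!is.finite(entries[!mask]))) stop("unmasked entries must be finite")
  if (any(entries[!mask] < 0)) stop("unmasked entries must be non-negative")
  if (kind == "observed" &&
      any(abs(entries[!mask] - round(entries[!mask])) > 1e-8))
    stop("observed spectra must hold integer counts")
  structure(list(entries = entries, sample_sizes = sample_sizes,
                 mask = mask, kind = kind, pop_labels = pop_labels),
            class = "afs")
}

.mask_corners <- function(mask) {
  if (is.matrix(mask)) {
    mask[1, 1] <- TRUE
    mask[nrow(mask), ncol(mask)] <- TRUE
  } else {
    mask[1] <- TRUE
    mask[length(mask)] <- TRUE
  }
  mask
}

#' @export
print.afs <- function(x, ...) {
  cat(sprintf("<afs: %s, %d population%s, sample sizes [%s], %.6g segregating SNPs>\n",
              x$kind, length(x$sample_sizes),
              if (length(x$sample_sizes) > 1) "s" else "",
              paste(x$sample_sizes, collapse = ", "), total_snps(x)))
  invisible(x)
}

#' Total segregating SNPs in a spectrum
#'
#' Sum of all unmasked cells; masked cells (including the fixed corner
#' categories) never contribute.
#'
#' @param x an [afs] object.
#' @return a non-negative number.
#' @export
total_snps <- function(x) {
  stopifnot(inherits(x, "afs"))
  sum(x$entries[!x$mask])
}

#' Read or write a spectrum in SFS text format
#'
#' The de-facto standard unfolded SFS text dialect: a header line with the
#' array extents (`2n_i + 1` per dimension) followed by the word
#' `unfolded`, one line of whitespace-separated cell values in row-major
#' order (last population index varies fastest), and one line of `0`/`1`
#' mask flags in the same order.  Folded spectra are not supported.
#'
#' @param file path or connection.
#' @param kind kind recorded on the spectrum read back (the format itself
#'   does not distinguish expected from observed spectra).
#' @return `read_sfs` returns an [afs]; `write_sfs` returns `file`
#'   invisibly.
#' @export
read_sfs <- function(file, kind = c("expected", "observed")) {
  kind <- match.arg(kind)
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3) stop("malformed SFS file: need header, values and mask lines")
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  flag_at <- suppressWarnings(which(is.na(as.numeric(header)))[1])
  if (is.na(flag_at) || flag_at < 2) stop("malformed SFS header: ", lines[1])
  dims <- as.integer(header[seq_len(flag_at - 1)])
  flag <- header[flag_at]
  if (identical(flag, "folded")) stop("folded spectra are not supported")
  if (!identical(flag, "unfolded")) stop("malformed SFS header flag: ", flag)
  if (length(dims) > 2) stop("only one- and two-population spectra are supported")
  vals <- as.numeric(strsplit(trimws(lines[2]), "\\s+")[[1]])
  flags <- as.integer(strsplit(trimws(lines[3]), "\\s+")[[1]])
  if (length(vals) != prod(dims) || length(flags) != prod(dims))
    stop("SFS value/mask count does not match header extents")
  if (length(dims) == 2) {
    entries <- matrix(vals, nrow = dims[1], ncol = dims[2], byrow = TRUE)
    mask <- matrix(flags == 1L, nrow = dims[1], ncol = dims[2], byrow = TRUE)
  } else {
    entries <- vals
    mask <- flags == 1L
  }
  afs(entries, sample_sizes = dims - 1L, kind = kind, mask = mask)
}

#' @param x an [afs] object to serialise.
#' @rdname read_sfs
#' @export
write_sfs <- function(x, file) {
  stopifnot(inherits(x, "afs"))
  dims <- x$sample_sizes + 1L
  vals <- if (is.matrix(x$entries)) as.vector(t(x$entries)) else x$entries
  flags <- if (is.matrix(x$mask)) as.vector(t(x$mask)) else x$mask
  writeLines(c(paste(c(dims, "unfolded"), collapse = " "),
               paste(sprintf("%.17g", vals), collapse = " "),
               paste(as.integer(flags), collapse = " ")), con = file)
  invisible(file)
}
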
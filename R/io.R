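#' Read a SNP fragment file
#'
#' Two on-disk dialects are supported. \code{"dense"} holds one fragment per
#' line as a string over \code{0}, \code{1} and \code{-} (gap); all lines must
#' have equal width. \code{"hapcut"} is the block format used by graph-cut
#' style phasers: whitespace-separated fields
#' \code{n_blocks id (start alleles)+ qualities}, where each block gives the
#' 1-based index of its first SNP followed by its allele string, and the final
#' field is one Phred-33 quality character per covered allele. Qualities are
#' decoded to per-entry error probabilities \code{q = 10^(-(ascii-33)/10)}.
#'
#' @param path file to read.
#' @param dialect \code{"hapcut"} or \code{"dense"}.
#' @param n_snps optional total number of SNP sites (hapcut only); defaults to
#'   the largest covered index.
#' @return a \code{\link{fragment_matrix}}.
#' @export
read_fragments <- function(path, dialect = c("dense", "hapcut"), n_snps = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("fragment file does not exist: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (dialect == "dense") read_dense(lines) else read_hapcut(lines, n_snps)
}

read_dense <- function(lines) {
  if (length(lines) == 0) {
    return(fragment_matrix(matrix(integer(), 0, 0)))
  }
  widths <- nchar(lines)
  if (length(unique(widths)) != 1) {
    bad <- which(widths != widths[1])[1]
    stop(sprintf("line %d: ragged row width (%d, expected %d)",
                 bad, widths[bad], widths[1]))
  }
  chars <- matrix(unlist(strsplit(lines, "", fixed = TRUE), use.names = FALSE),
                  nrow = length(lines), byrow = TRUE)
  ok <- chars %in% c("0", "1", "-")
  if (!all(ok)) {
    bad <- which(!matrix(ok, nrow = nrow(chars)), arr.ind = TRUE)[1, ]
    stop(sprintf("line %d: invalid allele character '%s'",
                 bad[1], chars[bad[1], bad[2]]))
  }
  m <- matrix(NA_integer_, nrow(chars), ncol(chars))
  m[chars == "0"] <- 0L
  m[chars == "1"] <- 1L
  fragment_matrix(m)
}

read_hapcut <- function(lines, n_snps = NULL) {
  frags <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    nb <- suppressWarnings(as.integer(tok[1]))
    if (is.na(nb) || nb < 1) stop(sprintf("line %d: invalid block count", i))
    if (length(tok) != 2 + 2 * nb + 1) {
      stop(sprintf("line %d: expected %d fields, found %d",
                   i, 2 + 2 * nb + 1, length(tok)))
    }
    id <- tok[2]
    cols <- integer(0); alle <- integer(0)
    for (b in seq_len(nb)) {
      start <- suppressWarnings(as.integer(tok[2 * b + 1]))
      astr <- tok[2 * b + 2]
      if (is.na(start) || start < 1) {
        stop(sprintf("line %d: invalid block start '%s'", i, tok[2 * b + 1]))
      }
      a <- strsplit(astr, "")[[1]]
      if (!all(a %in% c("0", "1"))) {
        stop(sprintf("line %d: invalid allele character in '%s'", i, astr))
      }
      cols <- c(cols, start + seq_along(a) - 1L)
      alle <- c(alle, as.integer(a))
    }
    qstr <- tok[length(tok)]
    if (nchar(qstr) != length(alle)) {
      stop(sprintf("line %d: %d quality characters for %d alleles",
                   i, nchar(qstr), length(alle)))
    }
    q <- 10^(-(utf8ToInt(qstr) - 33) / 10)
    q <- pmin(q, 1 - 1e-6)  # Phred 0 would decode to exactly 1
    if (anyDuplicated(cols)) stop(sprintf("line %d: overlapping blocks", i))
    frags[[i]] <- list(id = id, cols = cols, alle = alle, q = q)
  }
  n <- if (is.null(n_snps)) {
    max(c(0L, unlist(lapply(frags, `[[`, "cols"))))
  } else as.integer(n_snps)
  m <- matrix(NA_integer_, length(frags), n)
  qm <- matrix(NA_real_, length(frags), n)
  for (i in seq_along(frags)) {
    f <- frags[[i]]
    if (length(f$cols) && max(f$cols) > n) {
      stop(sprintf("line %d: SNP index %d exceeds n_snps = %d",
                   i, max(f$cols), n))
    }
    m[i, f$cols] <- f$alle
    qm[i, f$cols] <- f$q
  }
  fragment_matrix(m, error_probs = if (length(frags)) qm,
                  fragment_ids = vapply(frags, `[[`, "", "id"))
}

#' Write a SNP fragment file
#'
#' Inverse of \code{\link{read_fragments}}; \code{read(write(X))} reproduces
#' the allele entries bit-exactly in both dialects (and the error
#' probabilities in the hapcut dialect whenever they sit on the Phred grid).
#' Fragments with no covered SNP cannot be represented in the hapcut dialect.
#'
#' @param x a \code{\link{fragment_matrix}}.
#' @param path output file.
#' @param dialect \code{"hapcut"} or \code{"dense"}.
#' @param default_q error probability used for hapcut qualities when
#'   \code{x$error_probs} is absent.
#' @return \code{path}, invisibly.
#' @export
write_fragments <- function(x, path, dialect = c("dense", "hapcut"),
                            default_q = 0.05) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(x, "fragment_matrix"))
  if (dialect == "dense") {
    ch <- matrix("-", nrow(x$alleles), ncol(x$alleles))
    ch[!is.na(x$alleles)] <- as.character(x$alleles[!is.na(x$alleles)])
    lines <- apply(ch, 1, paste, collapse = "")
    if (nrow(x$alleles) == 0) lines <- character(0)
  } else {
    lines <- vapply(seq_len(nrow(x$alleles)), function(i) {
      row <- x$alleles[i, ]
      cov <- which(!is.na(row))
      if (!length(cov)) {
        stop(sprintf("fragment %d covers no SNP; not representable in hapcut dialect", i))
      }
      breaks <- c(0, which(diff(cov) > 1), length(cov))
      blocks <- lapply(seq_len(length(breaks) - 1), function(b) {
        cov[(breaks[b] + 1):breaks[b + 1]]
      })
      id <- if (!is.null(x$fragment_ids)) x$fragment_ids[i] else sprintf("f%d", i)
      q <- if (!is.null(x$error_probs)) x$error_probs[i, cov] else rep(default_q, length(cov))
      qchr <- intToUtf8(pmax(33L, pmin(126L, as.integer(round(-10 * log10(q))) + 33L)))
      paste(c(length(blocks), id,
              unlist(lapply(blocks, function(cols) {
                c(cols[1], paste(row[cols], collapse = ""))
              })),
              qchr), collapse = " ")
    }, "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read / write haplotype files
#'
#' Plain text: one binary string per haplotype row, all rows of equal length.
#'
#' @param path file location.
#' @return \code{read_haplotypes}: a \code{\link{haplotype_set}}.
#' @export
read_haplotypes <- function(path) {
  if (!file.exists(path)) stop("haplotype file does not exist: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("haplotype file is empty")
  widths <- nchar(lines)
  if (length(unique(widths)) != 1) {
    stop("ragged haplotype rows: lengths ", paste(unique(widths), collapse = ", "))
  }
  chars <- matrix(unlist(strsplit(lines, "", fixed = TRUE), use.names = FALSE),
                  nrow = length(lines), byrow = TRUE)
  if (!all(chars %in% c("0", "1"))) {
    stop("haplotype files may contain only 0/1 characters")
  }
  haplotype_set(matrix(as.integer(chars), nrow = nrow(chars)))
}

#' @rdname read_haplotypes
#' @param h a \code{\link{haplotype_set}}.
#' @export
write_haplotypes <- function(h, path) {
  stopifnot(inherits(h, "haplotype_set"))
  writeLines(apply(unclass(h), 1, paste, collapse = ""), path)
  invisible(path)
}

#' Read a genotype file (one allele-count integer per line or whitespace
#' separated), as written by \code{\link{write_instance}}.
#' @param path file location.
#' @return integer vector of per-site counts of the `1` allele.
#' @export
read_genotype <- function(path) {
  g <- scan(path, what = integer(), quiet = TRUE)
  as.integer(g)
}
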
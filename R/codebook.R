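# Codebooks --------------------------------------------------------------------
#
# The codebook B is a binary (R x C x J) tensor: barcode j is expected to
# fluoresce in channel c at round r iff B[r, c, j] == 1. "Unused" barcodes are
# valid codes absent from the experiment; their fitted densities calibrate the
# spot-calling threshold.

#' Construct a codebook
#'
#' @param B Binary array of dimension `R x C x J`.
#' @param gene_names Character vector of length `J` (unique). Defaults to
#'   `gene1..geneJ`, with unused barcodes named `unused1..`.
#' @param unused Logical vector of length `J` flagging unused barcodes.
#' @return An object of class `codebook`.
#' @export
codebook <- function(B, gene_names = NULL, unused = NULL) {
  stopifnot(is.array(B), length(dim(B)) == 3L)
  if (!all(B %in% c(0, 1))) stop("codebook entries must be 0 or 1", call. = FALSE)
  J <- dim(B)[3L]
  if (is.null(unused)) unused <- rep(FALSE, J)
  stopifnot(length(unused) == J)
  if (is.null(gene_names)) {
    gene_names <- character(J)
    gene_names[!unused] <- paste0("gene", seq_len(sum(!unused)))
    if (any(unused)) gene_names[unused] <- paste0("unused", seq_len(sum(unused)))
  }
  if (anyDuplicated(gene_names)) stop("duplicate gene names", call. = FALSE)
  stopifnot(length(gene_names) == J)
  active <- apply(B, 3L, sum)
  if (any(active == 0)) {
    stop("every barcode needs at least one active (round, channel) entry",
         call. = FALSE)
  }
  structure(
    list(B = B, gene_names = as.character(gene_names), unused = as.logical(unused)),
    class = "codebook"
  )
}

#' @export
print.codebook <- function(x, ...) {
  d <- dim(x$B)
  cat(sprintf("<codebook> %d barcodes (%d unused), %d rounds x %d channels%s\n",
              d[3L], sum(x$unused), d[1L], d[2L],
              if (is_one_hot(x)) ", one-hot per round" else ""))
  invisible(x)
}

n_barcodes <- function(cb) dim(cb$B)[3L]
cb_rounds  <- function(cb) dim(cb$B)[1L]
cb_channels <- function(cb) dim(cb$B)[2L]

#' Is each (round, barcode) slice one-hot?
#'
#' @param cb A `codebook`.
#' @return `TRUE` if every barcode activates exactly one channel per round.
#' @export
is_one_hot <- function(cb) {
  stopifnot(inherits(cb, "codebook"))
  all(apply(cb$B, c(1L, 3L), sum) == 1)
}

# (R*C) x J matrix form, row index (r-1)*C + c
codebook_matrix <- function(B) {
  d <- dim(B)
  matrix(aperm(B, c(2L, 1L, 3L)), d[1L] * d[2L], d[3L])
}

# rounds in which two one-hot barcodes differ
round_difference <- function(b1, b2) {
  sum(apply(b1 != b2, 1L, any))
}

#' Append unused barcodes to a codebook
#'
#' Enumerates (implicitly) all barcodes with exactly one active channel per
#' round and samples, uniformly among those still valid, codes that differ
#' from every barcode already in the book — and from each other — in at least
#' `min_round_diff` rounds.
#'
#' @param cb A one-hot-per-round `codebook`.
#' @param n_unused Number of unused barcodes to append (default 2).
#' @param min_round_diff Minimum number of differing rounds between any pair
#'   (default 3).
#' @param seed Integer seed controlling the uniform draw.
#' @return A `codebook` with `n_unused` additional barcodes flagged unused.
#' @export
augment_codebook <- function(cb, n_unused = 2L, min_round_diff = 3L, seed = 1L) {
  stopifnot(inherits(cb, "codebook"), n_unused >= 0L, min_round_diff >= 1L)
  if (n_unused == 0L) return(cb)
  if (n_barcodes(cb) > 0L && !is_one_hot(cb)) {
    stop("augment_codebook requires a one-hot-per-round codebook", call. = FALSE)
  }
  R <- cb_rounds(cb); C <- cb_channels(cb)
  if (min_round_diff > R) {
    stop(sprintf("barcodes over %d rounds cannot differ in %d rounds; found 0 of %d",
                 R, min_round_diff, n_unused), call. = FALSE)
  }
  if (C^R > 2e6) {
    stop("candidate barcode space too large to enumerate; reduce rounds/channels",
         call. = FALSE)
  }
  # all one-hot codes as an R-column matrix of channel indices (1-based)
  cand <- as.matrix(expand.grid(rep(list(seq_len(C)), R)))
  existing <- one_hot_channels(cb)
  picked <- matrix(NA_integer_, 0L, R)
  withr::with_seed(seed, {
    for (k in seq_len(n_unused)) {
      ref <- rbind(existing, picked)
      ok <- rep(TRUE, nrow(cand))
      if (nrow(ref) > 0L) {
        for (i in seq_len(nrow(ref))) {
          diffs <- rowSums(cand != matrix(ref[i, ], nrow(cand), R, byrow = TRUE))
          ok <- ok & (diffs >= min_round_diff)
          if (!any(ok)) break
        }
      }
      idx <- which(ok)
      if (length(idx) == 0L) {
        stop(sprintf("candidate pool exhausted: found %d of %d unused barcodes",
                     k - 1L, n_unused), call. = FALSE)
      }
      picked <- rbind(picked, cand[idx[sample.int(length(idx), 1L)], ])
    }
  })
  Bnew <- array(0, dim = c(R, C, n_barcodes(cb) + n_unused))
  if (n_barcodes(cb) > 0L) Bnew[, , seq_len(n_barcodes(cb))] <- cb$B
  for (k in seq_len(n_unused)) {
    for (r in seq_len(R)) Bnew[r, picked[k, r], n_barcodes(cb) + k] <- 1
  }
  codebook(
    Bnew,
    gene_names = c(cb$gene_names,
                   paste0("unused", sum(cb$unused) + seq_len(n_unused))),
    unused = c(cb$unused, rep(TRUE, n_unused))
  )
}

# channel index per round for one-hot barcodes (rows = barcodes)
one_hot_channels <- function(cb) {
  J <- n_barcodes(cb); R <- cb_rounds(cb)
  out <- matrix(NA_integer_, J, R)
  for (j in seq_len(J)) {
    for (r in seq_len(R)) out[j, r] <- which(cb$B[r, , j] == 1)[1L]
  }
  out
}

#' Random one-hot codebook
#'
#' Convenience generator for simulations: `J` distinct one-hot-per-round
#' barcodes drawn uniformly.
#'
#' @param R,C,J Rounds, channels, number of barcodes.
#' @param seed Integer seed.
#' @return A `codebook`.
#' @export
random_codebook <- function(R, C, J, seed = 1L) {
  stopifnot(J <= C^R)
  withr::with_seed(seed, {
    seen <- character(0)
    rows <- matrix(NA_integer_, 0L, R)
    while (nrow(rows) < J) {
      cand <- sample.int(C, R, replace = TRUE)
      key <- paste(cand, collapse = ",")
      if (!key %in% seen) {
        seen <- c(seen, key)
        rows <- rbind(rows, cand)
      }
    }
    B <- array(0, dim = c(R, C, J))
    for (j in seq_len(J)) for (r in seq_len(R)) B[r, rows[j, r], j] <- 1
    codebook(B)
  })
}

#' Color-balanced one-hot codebook
#'
#' Generates `J` distinct one-hot-per-round barcodes with each round's
#' channel usage as even as possible (each channel used `J/C` times per
#' round, up to rounding). Experimental codebooks are designed this way so
#' that every (round, channel) frame carries signal, which keeps the
#' per-frame gains identifiable.
#'
#' @param R,C,J Rounds, channels, number of barcodes.
#' @param seed Integer seed.
#' @return A `codebook`.
#' @export
balanced_codebook <- function(R, C, J, seed = 1L) {
  stopifnot(J <= C^R)
  withr::with_seed(seed, {
    for (attempt in 1:100) {
      rows <- vapply(seq_len(R), function(r) sample(rep_len(seq_len(C), J)),
                     integer(J))             # J x R channel assignments
      if (!anyDuplicated(rows)) break
    }
    if (anyDuplicated(rows)) {
      stop("could not draw distinct balanced barcodes; increase C or R",
           call. = FALSE)
    }
    B <- array(0, dim = c(R, C, J))
    for (j in seq_len(J)) for (r in seq_len(R)) B[r, rows[j, r], j] <- 1
    codebook(B)
  })
}

#' Tidy a codebook into a long tibble
#'
#' @param x A `codebook`.
#' @param ... Unused.
#' @return A tibble with one row per active (gene, round, channel) entry,
#'   0-based `round`/`channel`.
#' @method tidy codebook
#' @export
tidy.codebook <- function(x, ...) {
  idx <- which(x$B == 1, arr.ind = TRUE)
  tibble::tibble(
    gene = x$gene_names[idx[, 3L]],
    barcode_index = idx[, 3L] - 1L,
    round = idx[, 1L] - 1L,
    channel = idx[, 2L] - 1L,
    unused = x$unused[idx[, 3L]]
  ) |> dplyr::arrange(.data$barcode_index, .data$round)
}
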
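# Readers and writers ----------------------------------------------------------
#
# Stack formats:
#  * TIFF directory: one float TIFF per frame named r{round}_c{channel}.tif
#    (0-based). writeTIFF stores 32-bit samples in [0, 1], so frames are
#    divided by a single per-stack scale recorded in scale.txt alongside a
#    shape.txt with "R C <spatial extents>". Values round-trip to float32
#    precision.
#  * CSV: long form with header round,channel,<axes...>,value (all indices
#    0-based); doubles are printed at full precision, so the round trip is
#    bit-exact.
# Codebook CSV dialects:
#  * wide: gene,round1..roundR, each cell a 0-based active-channel index
#    (one-hot-per-round);
#  * long: gene,round,channel rows for general binary codebooks.
# All writers are atomic (write to a temp path in the same directory, then
# rename).

#' Write an image stack
#'
#' @param X An `image_stack`.
#' @param path Target path: a directory for `format = "tiff"`, a file for
#'   `format = "csv"`.
#' @param format `"tiff"` (float32 frames plus scale/shape sidecars) or
#'   `"csv"` (lossless long form).
#' @return `path`, invisibly.
#' @export
write_stack <- function(X, path, format = c("tiff", "csv")) {
  stopifnot(inherits(X, "image_stack"))
  format <- match.arg(format)
  if (format == "tiff") {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    scale <- max(X$data, 1e-300)
    for (r in seq_len(X$R)) {
      for (cc in seq_len(X$C)) {
        frame <- unflatten_spatial(X$data[, rc_index(r, cc, X$C)],
                                   X$spatial_shape) / scale
        f <- file.path(path, sprintf("r%d_c%d.tif", r - 1L, cc - 1L))
        tmp <- tempfile(tmpdir = path, fileext = ".tif")
        if (length(dim(frame)) == 3L) {
          tiff::writeTIFF(lapply(seq_len(dim(frame)[1L]),
                                 function(z) frame[z, , ]),
                          tmp, bits.per.sample = 32L)
        } else {
          tiff::writeTIFF(frame, tmp, bits.per.sample = 32L)
        }
        file.rename(tmp, f)
      }
    }
    atomic_write_lines(format(scale, digits = 17), file.path(path, "scale.txt"))
    atomic_write_lines(paste(c(X$R, X$C, X$spatial_shape), collapse = " "),
                       file.path(path, "shape.txt"))
  } else {
    df <- tidy.image_stack(X)
    atomic_write_csv(df, path, digits = 17)
  }
  invisible(path)
}

#' Read an image stack
#'
#' Accepts a TIFF frame directory or a long-form CSV, as produced by
#' [write_stack()]. Negative values are clamped to zero with a warning
#' reporting how many were affected.
#'
#' @param path Directory (TIFF) or file (CSV) path.
#' @return An `image_stack`.
#' @export
read_stack <- function(path) {
  if (dir.exists(path)) read_stack_tiff(path) else read_stack_csv(path)
}

read_stack_tiff <- function(path) {
  shape_file <- file.path(path, "shape.txt")
  if (!file.exists(shape_file)) {
    stop(sprintf("missing %s", shape_file), call. = FALSE)
  }
  dims <- as.integer(strsplit(readLines(shape_file, n = 1L), "\\s+")[[1]])
  R <- dims[1L]; C <- dims[2L]; spatial <- dims[-(1:2)]
  scale_file <- file.path(path, "scale.txt")
  scale <- if (file.exists(scale_file)) as.numeric(readLines(scale_file, n = 1L)) else 1
  M <- prod(spatial)
  mat <- matrix(0, M, R * C)
  for (r in seq_len(R)) {
    for (cc in seq_len(C)) {
      f <- file.path(path, sprintf("r%d_c%d.tif", r - 1L, cc - 1L))
      if (!file.exists(f)) {
        stop(sprintf("missing frame r%d_c%d.tif", r - 1L, cc - 1L), call. = FALSE)
      }
      img <- tiff::readTIFF(f, all = length(spatial) == 3L)
      if (is.list(img)) {
        frame <- array(0, dim = spatial)
        if (length(img) != spatial[1L]) {
          stop(sprintf("frame r%d_c%d.tif has %d planes, expected %d",
                       r - 1L, cc - 1L, length(img), spatial[1L]), call. = FALSE)
        }
        for (z in seq_along(img)) frame[z, , ] <- img[[z]]
      } else {
        frame <- img
      }
      if (!all(dim(frame) == spatial)) {
        stop(sprintf("frame r%d_c%d.tif has inconsistent shape", r - 1L, cc - 1L),
             call. = FALSE)
      }
      mat[, rc_index(r, cc, C)] <- flatten_spatial(frame) * scale
    }
  }
  clamp_negatives(mat, R, C, spatial)
}

read_stack_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("round", "channel", "value")
  if (!all(need %in% names(df))) {
    stop("stack CSV must have columns round, channel, <axes>, value", call. = FALSE)
  }
  axes <- setdiff(names(df), need)
  d <- length(axes)
  if (d < 2L || d > 3L) stop("stack CSV needs 2 or 3 coordinate columns", call. = FALSE)
  R <- max(df$round) + 1L; C <- max(df$channel) + 1L
  spatial <- vapply(axes, function(a) max(df[[a]]) + 1L, integer(1))
  M <- prod(spatial)
  if (nrow(df) != M * R * C) {
    stop("stack CSV row count does not fill the (round, channel, voxel) grid",
         call. = FALSE)
  }
  m <- coords_to_voxel(as.matrix(df[, axes]), spatial)
  k <- df$round * C + df$channel + 1L
  mat <- matrix(0, M, R * C)
  mat[cbind(m + 1L, k)] <- df$value
  clamp_negatives(mat, R, C, spatial)
}

clamp_negatives <- function(mat, R, C, spatial) {
  n_neg <- sum(mat < 0)
  if (n_neg > 0) {
    warning(sprintf("clamped %d negative value%s to 0", n_neg,
                    if (n_neg == 1L) "" else "s"))
    mat <- pmax(mat, 0)
  }
  image_stack(mat, R = R, C = C, spatial_shape = spatial)
}

#' Write a codebook CSV
#'
#' One-hot codebooks are written in the wide dialect
#' (`gene,unused,round1..roundR` with 0-based channel indices), general
#' binary codebooks in the long dialect (`gene,unused,round,channel`).
#'
#' @param cb A `codebook`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_codebook <- function(cb, path) {
  stopifnot(inherits(cb, "codebook"))
  if (is_one_hot(cb)) {
    ch <- one_hot_channels(cb) - 1L
    df <- data.frame(gene = cb$gene_names, unused = as.integer(cb$unused))
    for (r in seq_len(cb_rounds(cb))) df[[paste0("round", r)]] <- ch[, r]
  } else {
    long <- tidy.codebook(cb)
    df <- data.frame(gene = long$gene, unused = as.integer(long$unused),
                     round = long$round, channel = long$channel)
  }
  atomic_write_csv(df, path)
  invisible(path)
}

#' Read a codebook CSV
#'
#' Accepts the wide dialect (`gene,round1..roundR`, each cell a 0-based
#' active-channel index) or the long dialect (`gene,round,channel`). An
#' optional `unused` column (0/1) flags unused barcodes.
#'
#' @param path Codebook CSV file.
#' @param n_channels Number of channels `C`; default: one more than the
#'   largest channel index present.
#' @return A `codebook`.
#' @export
read_codebook <- function(path, n_channels = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"gene" %in% names(df)) stop("codebook CSV needs a gene column", call. = FALSE)
  long_form <- all(c("round", "channel") %in% names(df))
  if (long_form) {
    genes <- unique(df$gene)
    R <- max(df$round) + 1L
    C <- n_channels %||% (max(df$channel) + 1L)
    if (any(df$channel >= C)) stop("channel index out of range", call. = FALSE)
    J <- length(genes)
    B <- array(0, dim = c(R, C, J))
    for (i in seq_len(nrow(df))) {
      B[df$round[i] + 1L, df$channel[i] + 1L, match(df$gene[i], genes)] <- 1
    }
    unused <- if ("unused" %in% names(df)) {
      vapply(genes, function(g) any(df$unused[df$gene == g] == 1), logical(1))
    } else rep(FALSE, J)
    codebook(B, gene_names = genes, unused = unused)
  } else {
    round_cols <- grep("^round[0-9]+$", names(df), value = TRUE)
    if (length(round_cols) == 0L) {
      stop("codebook CSV needs round1..roundR columns (wide) or round,channel (long)",
           call. = FALSE)
    }
    round_cols <- round_cols[order(as.integer(sub("round", "", round_cols)))]
    if (anyDuplicated(df$gene)) stop("duplicate gene names in codebook", call. = FALSE)
    R <- length(round_cols)
    ch <- as.matrix(df[, round_cols, drop = FALSE])
    if (any(is.na(ch))) stop("ragged or non-numeric codebook rows", call. = FALSE)
    C <- n_channels %||% (max(ch) + 1L)
    if (any(ch >= C) || any(ch < 0)) stop("channel index out of range", call. = FALSE)
    J <- nrow(df)
    B <- array(0, dim = c(R, C, J))
    for (j in seq_len(J)) for (r in seq_len(R)) B[r, ch[j, r] + 1L, j] <- 1
    unused <- if ("unused" %in% names(df)) df$unused == 1 else rep(FALSE, J)
    codebook(B, gene_names = df$gene, unused = unused)
  }
}

#' Write the standard result bundle
#'
#' Three outputs: (1) the spot CSV (`spots.csv`); (2) a diagnostics directory
#' (`diagnostics/`) holding the fitted parameters and per-spot quality
#' records as plain-text tables plus a `meta.yaml`; (3) the quality histogram
#' (`quality_histogram.csv` and, when ggplot2 rendering succeeds,
#' `quality_histogram.pdf`).
#'
#' @param fit A `density_fit`.
#' @param spots A `spot_table`.
#' @param qualities Tibble from [spot_qualities()] (may be `NULL` to skip
#'   quality outputs).
#' @param dir Output directory (created if missing; must be writable).
#' @return `dir`, invisibly.
#' @export
write_outputs <- function(fit, spots, qualities = NULL, dir) {
  stopifnot(inherits(fit, "density_fit"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop(sprintf("cannot create output directory %s", dir), call. = FALSE)
  }
  probe <- tempfile(tmpdir = dir)
  ok <- tryCatch({ file.create(probe) }, warning = function(w) FALSE)
  if (!isTRUE(ok)) stop(sprintf("output directory %s is not writable", dir), call. = FALSE)
  unlink(probe)

  spot_df <- as.data.frame(spots[, setdiff(names(spots), "quality")])
  atomic_write_csv(spot_df, file.path(dir, "spots.csv"), digits = 17)

  diag_dir <- file.path(dir, "diagnostics")
  if (!dir.exists(diag_dir)) dir.create(diag_dir)
  p <- fit$params
  atomic_write_csv(data.frame(voxel = seq_len(nrow(p$F)) - 1L, a = p$a),
                   file.path(diag_dir, "background.csv"), digits = 17)
  frame_df <- data.frame(
    round = rep(seq_len(fit$R) - 1L, each = fit$C),
    channel = rep(seq_len(fit$C) - 1L, fit$R),
    b = rc_vec(p$b), alpha = rc_vec(p$alpha)
  )
  atomic_write_csv(frame_df, file.path(diag_dir, "frame_params.csv"), digits = 17)
  atomic_write_csv(as.data.frame(p$phi), file.path(diag_dir, "phi.csv"), digits = 17)
  atomic_write_csv(data.frame(channel = seq_along(p$rho) - 1L, rho = p$rho),
                   file.path(diag_dir, "rho.csv"), digits = 17)
  nz <- which(p$F > 0, arr.ind = TRUE)
  dens_df <- data.frame(voxel = nz[, 1L] - 1L, barcode_index = nz[, 2L] - 1L,
                        density = p$F[nz])
  atomic_write_csv(dens_df, file.path(diag_dir, "densities.csv"), digits = 17)
  meta <- list(rounds = fit$R, channels = fit$C,
               spatial_shape = as.integer(fit$spatial_shape),
               omega = fit$omega, lambda = fit$lambda,
               reconstruction_loss = fit$reconstruction_loss,
               sparsity_loss = fit$sparsity_loss,
               converged = fit$converged)
  tmp <- tempfile(tmpdir = diag_dir)
  yaml::write_yaml(meta, tmp)
  file.rename(tmp, file.path(diag_dir, "meta.yaml"))

  if (!is.null(qualities)) {
    qh <- quality_histogram(qualities)
    atomic_write_csv(as.data.frame(qh), file.path(dir, "quality_histogram.csv"))
    qdf <- as.data.frame(qualities[, setdiff(names(qualities), "quality")])
    atomic_write_csv(qdf, file.path(diag_dir, "spot_quality.csv"), digits = 17)
    tv <- t(vapply(qualities$quality, function(q) q$temporal_vector,
                   numeric(fit$R * fit$C)))
    colnames(tv) <- sprintf("r%d_c%d",
                            rep(seq_len(fit$R) - 1L, each = fit$C),
                            rep(seq_len(fit$C) - 1L, fit$R))
    atomic_write_csv(as.data.frame(tv),
                     file.path(diag_dir, "temporal_vectors.csv"), digits = 17)
    try({
      pl <- ggplot2::autoplot(qh)
      tmp <- tempfile(tmpdir = dir, fileext = ".pdf")
      ggplot2::ggsave(tmp, pl, width = 5, height = 4)
      file.rename(tmp, file.path(dir, "quality_histogram.pdf"))
    }, silent = TRUE)
  }
  invisible(dir)
}

atomic_write_csv <- function(df, path, digits = NULL) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".csv")
  if (!is.null(digits)) {
    num <- vapply(df, is.double, logical(1))
    df[num] <- lapply(df[num], function(x) format(x, digits = digits,
                                                  scientific = FALSE, trim = TRUE))
  }
  utils::write.csv(df, tmp, row.names = FALSE, quote = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

atomic_write_lines <- function(lines, path) {
  tmp <- tempfile(tmpdir = dirname(path))
  writeLines(lines, tmp)
  file.rename(tmp, path)
  invisible(path)
}
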
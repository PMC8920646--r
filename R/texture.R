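# Gray-level co-occurrence texture features computed on the minimum bounding
# rectangle around the lesion in the envelope image: 16-level linear
# quantization, directed GLCMs at distances 1-5 and angles 0/45/90/135
# degrees, and contrast / correlation / energy / homogeneity averaged over
# all 20 (distance, angle) matrices.

#' Quantize an envelope ROI into discrete gray levels
#'
#' The full value range of the bounding-box ROI is linearly scaled into `L`
#' levels: `level = 1 + floor((v - min) * L / (max - min))`, clipped to
#' `[1, L]`. A constant ROI maps entirely to level 1 and is flagged.
#'
#' @param envelope envelope image matrix
#' @param mask an [roi_mask] on the same grid; its tight bounding rectangle
#'   defines the ROI (pixels inside the box but outside the mask are kept)
#' @param levels number of gray levels (default 16)
#' @return integer matrix of levels with attributes `origin` (top-left of
#'   the box) and `degenerate`
#' @export
quantize_roi <- function(envelope, mask, levels = 16L) {
  stopifnot(inherits(mask, "roi_mask"))
  if (!identical(dim(envelope), dim(mask$mask)))
    stopf("envelope and mask shapes differ")
  rows <- range(which(rowSums(mask$mask) > 0))
  cols <- range(which(colSums(mask$mask) > 0))
  box <- envelope[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
  if (length(box) == 0L) stopf("empty bounding box")
  lo <- min(box); hi <- max(box)
  if (hi <= lo) {
    q <- matrix(1L, nrow(box), ncol(box))
    return(structure(q, origin = c(rows[1], cols[1]), degenerate = TRUE))
  }
  q <- 1L + floor((box - lo) * levels / (hi - lo))
  q[q > levels] <- levels
  storage.mode(q) <- "integer"
  structure(q, origin = c(rows[1], cols[1]), degenerate = FALSE,
            levels = as.integer(levels))
}

# pixel offset (row, col) implied by a distance and angle; row index grows
# downward, so 45 degrees looks up-right
glcm_offset <- function(distance, angle) {
  switch(as.character(angle),
         "0"   = c(0L, distance),
         "45"  = c(-distance, distance),
         "90"  = c(-distance, 0L),
         "135" = c(-distance, -distance),
         stopf("angle must be one of 0, 45, 90, 135"))
}

#' Compute a directed gray-level co-occurrence matrix
#'
#' Counts how often a pixel with level `i` has a pixel with level `j` at the
#' offset implied by `(distance, angle)`, then normalizes the counts to sum
#' to one. Pairs whose partner falls outside the ROI are skipped.
#'
#' @param q quantized ROI from [quantize_roi]
#' @param distance interpixel distance in 1..5
#' @param angle direction in degrees: 0, 45, 90 or 135
#' @param levels number of gray levels (default: from `q`, else 16)
#' @return `levels x levels` matrix of class `glcm` summing to 1
#' @export
compute_glcm <- function(q, distance, angle, levels = NULL) {
  if (!distance %in% 1:5) stopf("distance must be in 1..5")
  levels <- as.integer(levels %||% attr(q, "levels") %||% 16L)
  off <- glcm_offset(as.integer(distance), angle)
  nr <- nrow(q); nc <- ncol(q)
  rlo <- max(1L, 1L - off[1]); rhi <- min(nr, nr - off[1])
  clo <- max(1L, 1L - off[2]); chi <- min(nc, nc - off[2])
  if (rlo > rhi || clo > chi)
    stopf("ROI smaller than the (distance, angle) offset")
  r1 <- rlo:rhi
  c1 <- clo:chi
  from <- q[r1, c1, drop = FALSE]
  to <- q[r1 + off[1], c1 + off[2], drop = FALSE]
  if (length(from) == 0L) stopf("ROI smaller than the (distance, angle) offset")
  counts <- matrix(tabulate((as.vector(to) - 1L) * levels + as.vector(from),
                            nbins = levels * levels),
                   levels, levels)
  structure(counts / sum(counts), class = "glcm",
            distance = as.integer(distance), angle = angle)
}

#' Texture features of a normalized GLCM
#'
#' Contrast `sum (i-j)^2 P(i,j)`; correlation
#' `sum (i - mu_i)(j - mu_j) P(i,j) / (sigma_i sigma_j)` with row/column
#' marginal means and standard deviations (flagged undefined when either
#' marginal is degenerate); energy `sum P^2`; homogeneity
#' `sum P(i,j) / (1 + |i-j|)`.
#'
#' @param P normalized GLCM (entries summing to 1)
#' @return named list `contrast`, `correlation`, `energy`, `homogeneity`,
#'   plus `correlation_defined`
#' @export
glcm_features <- function(P) {
  P <- unclass(P)
  if (abs(sum(P) - 1) > 1e-8) stopf("GLCM must be normalized to sum 1")
  L <- nrow(P)
  i <- matrix(seq_len(L), L, L)
  j <- t(i)
  pi_ <- rowSums(P)
  pj_ <- colSums(P)
  mui <- sum(seq_len(L) * pi_)
  muj <- sum(seq_len(L) * pj_)
  si <- sqrt(sum((seq_len(L) - mui)^2 * pi_))
  sj <- sqrt(sum((seq_len(L) - muj)^2 * pj_))
  corr_def <- si > 0 && sj > 0
  list(contrast = sum((i - j)^2 * P),
       correlation = if (corr_def) sum((i - mui) * (j - muj) * P) / (si * sj)
                     else NA_real_,
       energy = sum(P^2),
       homogeneity = sum(P / (1 + abs(i - j))),
       correlation_defined = corr_def)
}

#' Averaged GLCM texture features of a lesion
#'
#' Quantizes the bounding-box ROI to 16 levels, computes the 20 directed
#' GLCMs (distances 1-5 x angles 0/45/90/135) and returns the arithmetic
#' mean of each feature. Undefined correlations are excluded from the
#' correlation mean (error if all 20 are undefined).
#'
#' @param envelope envelope image matrix
#' @param mask intratumoral [roi_mask] on the same grid
#' @param levels gray levels (default 16)
#' @param distances,angles offsets to average over
#' @return named list `contrast`, `correlation`, `energy`, `homogeneity`
#' @export
averaged_texture_features <- function(envelope, mask, levels = 16L,
                                      distances = 1:5,
                                      angles = c(0, 45, 90, 135)) {
  q <- quantize_roi(envelope, mask, levels)
  if (nrow(q) < max(distances) + 1L || ncol(q) < max(distances) + 1L)
    stopf("bounding box %dx%d is too small for distance %d",
          nrow(q), ncol(q), max(distances))
  feats <- list(contrast = c(), correlation = c(), energy = c(), homogeneity = c())
  for (d in distances) for (a in angles) {
    fx <- glcm_features(compute_glcm(q, d, a, levels))
    feats$contrast <- c(feats$contrast, fx$contrast)
    feats$correlation <- c(feats$correlation,
                           if (fx$correlation_defined) fx$correlation else NA_real_)
    feats$energy <- c(feats$energy, fx$energy)
    feats$homogeneity <- c(feats$homogeneity, fx$homogeneity)
  }
  corr <- feats$correlation[!is.na(feats$correlation)]
  if (length(corr) == 0L)
    stopf("correlation undefined for every (distance, angle) pair (constant ROI)")
  if (length(corr) < length(feats$correlation))
    warnf("correlation undefined for %d of %d GLCMs; excluded from the mean",
          length(feats$correlation) - length(corr), length(feats$correlation))
  list(contrast = mean(feats$contrast),
       correlation = mean(corr),
       energy = mean(feats$energy),
       homogeneity = mean(feats$homogeneity))
}
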
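#' GLCM settings for the Haralick texture features
#'
#' @param nLevels number of gray levels G; region pixels are quantized to
#'   1..G with uniform bins over the region's own [min, max].
#' @param distance co-occurrence offset distance in pixels.
#' @param tissue region on which the texture features are computed
#'   ("muscle" by default).
#' @return a list of class \code{glcmConfig}.
#' @export
glcmConfig <- function(nLevels = 32L, distance = 1L, tissue = "muscle") {
  stopifnot(nLevels >= 2L, distance >= 1L, tissue %in% c("muscle", "fat"))
  structure(list(nLevels = as.integer(nLevels), distance = as.integer(distance),
                 tissue = tissue), class = "glcmConfig")
}

HARALICK_NAMES <- c("haralick_asm", "haralick_contrast", "haralick_correlation",
                    "haralick_variance", "haralick_idm", "haralick_sum_average",
                    "haralick_sum_variance", "haralick_sum_entropy",
                    "haralick_entropy", "haralick_diff_variance",
                    "haralick_diff_entropy", "haralick_imc1", "haralick_imc2")

## quantize region pixels to 1..G, uniform bins over the region's [min, max];
## a constant region maps to a single level
.quantize <- function(values, G) {
  lo <- min(values); hi <- max(values)
  if (hi == lo) return(rep(1L, length(values)))
  pmin(G, as.integer(floor((values - lo) / (hi - lo) * G)) + 1L)
}

## symmetric pair counts for one offset; NULL when no in-region pair exists
.pairCounts <- function(Q, dr, dc, G) {
  nr <- nrow(Q); nc <- ncol(Q)
  r1 <- seq.int(max(1L, 1L - dr), min(nr, nr - dr))
  c1 <- seq.int(max(1L, 1L - dc), min(nc, nc - dc))
  if (length(r1) == 0L || length(c1) == 0L) return(NULL)
  A <- Q[r1, c1, drop = FALSE]
  B <- Q[r1 + dr, c1 + dc, drop = FALSE]
  ok <- !is.na(A) & !is.na(B)
  if (!any(ok)) return(NULL)
  C <- matrix(tabulate((A[ok] - 1L) * G + B[ok], nbins = G * G), nrow = G)
  C + t(C)  # symmetric GLCM: count each ordered pair both ways
}

## the 13 classical statistics of one normalized symmetric GLCM
## (natural logs; levels 1..G; sum variance taken about the sum average;
## correlation and IMC1 of a single-level GLCM defined as 0)
.haralickFromGLCM <- function(P) {
  G <- nrow(P)
  lev <- seq_len(G)
  i <- row(P); j <- col(P)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum(lev * px); muy <- sum(lev * py)
  sx <- sqrt(sum((lev - mux)^2 * px)); sy <- sqrt(sum((lev - muy)^2 * py))
  ks <- 2:(2 * G)
  psum <- vapply(ks, function(s) sum(P[i + j == s]), numeric(1))
  kd <- 0:(G - 1)
  pdiff <- vapply(kd, function(s) sum(P[abs(i - j) == s]), numeric(1))
  ent0 <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }

  asm <- sum(P^2)
  contrast <- sum(kd^2 * pdiff)
  correlation <- if (sx > 0 && sy > 0) (sum(i * j * P) - mux * muy) / (sx * sy) else 0
  variance <- sum((i - mux)^2 * P)
  idm <- sum(P / (1 + (i - j)^2))
  sum_average <- sum(ks * psum)
  sum_variance <- sum((ks - sum_average)^2 * psum)
  sum_entropy <- ent0(psum)
  entropy <- ent0(P)
  mu_d <- sum(kd * pdiff)
  diff_variance <- sum((kd - mu_d)^2 * pdiff)
  diff_entropy <- ent0(pdiff)
  hx <- ent0(px); hy <- ent0(py)
  pp <- outer(px, py)
  sel <- P > 0  # wherever P>0 the marginal product is > 0 too
  hxy1 <- -sum(P[sel] * log(pp[sel]))
  hxy2 <- ent0(pp)
  imc1 <- if (max(hx, hy) > 0) (entropy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - entropy))))

  stats::setNames(c(asm, contrast, correlation, variance, idm, sum_average,
                    sum_variance, sum_entropy, entropy, diff_variance,
                    diff_entropy, imc1, imc2), HARALICK_NAMES)
}

## normalized directional GLCMs (0, 45, 90, 135 degrees) of one tissue region
.glcmMatrices <- function(image, mask, tissue, config) {
  label <- c(muscle = 1, fat = 2)[[tissue]]
  inreg <- mask == label
  if (!any(inreg))
    .err(sprintf("no pixels labeled '%s' in mask", tissue), "empty_region_error")
  Q <- matrix(NA_integer_, nrow(image), ncol(image))
  Q[inreg] <- .quantize(image[inreg], config$nLevels)
  d <- config$distance
  offsets <- list(c(0L, d), c(-d, d), c(-d, 0L), c(-d, -d))
  mats <- lapply(offsets, function(o)
    .pairCounts(Q, o[1L], o[2L], config$nLevels))
  mats <- Filter(Negate(is.null), mats)
  lapply(mats, function(C) C / sum(C))
}

#' Haralick GLCM texture features of a tissue region
#'
#' Region pixels are quantized to \code{nLevels} gray levels (uniform bins
#' over the region's min--max), symmetric gray-level co-occurrence matrices
#' are accumulated at the configured distance for the four directions 0, 45,
#' 90 and 135 degrees -- counting only pixel pairs that both carry the
#' requested tissue label -- and the 13 classical statistics are computed per
#' direction and averaged across directions.
#'
#' @param image 2-D intensity matrix.
#' @param mask label matrix (0/1/2), or \code{NULL} to use the whole image.
#' @param tissue region to analyse; defaults to the config's tissue.
#' @param config a \code{\link{glcmConfig}}.
#' @return named numeric vector of the 13 statistics.
#' @export
haralickFeatures <- function(image, mask = NULL, tissue = NULL,
                             config = glcmConfig()) {
  if (is.null(mask)) {
    mask <- matrix(1, nrow(image), ncol(image))
    tissue <- "muscle"
  }
  tissue <- tissue %||% config$tissue
  if (!identical(dim(image), dim(mask)))
    .err("image and mask dimensions differ", "dimension_error")
  mats <- .glcmMatrices(image, mask, tissue, config)
  if (length(mats) == 0L)
    .err(sprintf("no co-occurring pixel pair inside the '%s' region at distance %d",
                 tissue, config$distance), "insufficient_pairs_error")
  rowMeans(vapply(mats, .haralickFromGLCM, numeric(13L)))
}
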
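# -- shared fixtures ---------------------------------------------------------

# tiny in-memory synthetic study; defaults keep unit tests fast
tinyStudy <- function(nN = 6L, nIBM = 6L, nPM = 0L, nDM = 0L,
                      muscles = c("deltoid", "rectus_femoris"),
                      views = 2L, px = 64L, seed = 3L,
                      preset = classPreset("separable")) {
  ns <- c(N = nN, PM = nPM, DM = nDM, IBM = nIBM)
  des <- studyDesign(nSubjects = ns[ns > 0L], muscles = muscles, views = views,
                     sizes = list(`4` = c(width = px, height = px),
                                  `6` = c(width = px, height = px)),
                     seed = seed)
  generateStudy(des, preset)
}

# subject roster matching the clinical cohort (one deltoid image per subject,
# enough to count subjects through the cohort filters)
rosterStudy <- function() {
  des <- studyDesign(nSubjects = c(N = 33L, PM = 14L, DM = 14L, IBM = 19L),
                     muscles = "deltoid", sides = "left", views = 1L,
                     sizes = list(`4` = c(width = 16L, height = 16L),
                                  `6` = c(width = 16L, height = 16L)),
                     seed = 1L)
  generateStudy(des, classPreset("null"))
}

# -- independent Haralick oracle --------------------------------------------
# Brute force: enumerate every ordered pixel pair at the offset, build the
# normalized symmetric GLCM by explicit loops, and apply the textbook
# formulas term by term (levels 1..G, natural logs, sum variance about the
# sum average). Shares no code with the package implementation.
oracleGLCM <- function(q, dr, dc, G) {
  P <- matrix(0, G, G)
  for (r in seq_len(nrow(q))) for (cc in seq_len(ncol(q))) {
    r2 <- r + dr; c2 <- cc + dc
    if (r2 >= 1 && r2 <= nrow(q) && c2 >= 1 && c2 <= ncol(q) &&
        !is.na(q[r, cc]) && !is.na(q[r2, c2])) {
      P[q[r, cc], q[r2, c2]] <- P[q[r, cc], q[r2, c2]] + 1
      P[q[r2, c2], q[r, cc]] <- P[q[r2, c2], q[r, cc]] + 1
    }
  }
  P / sum(P)
}

oracleHaralick13 <- function(P) {
  G <- nrow(P)
  px <- numeric(G); py <- numeric(G)
  for (i in 1:G) for (j in 1:G) { px[i] <- px[i] + P[i, j]; py[j] <- py[j] + P[i, j] }
  mux <- sum((1:G) * px); muy <- sum((1:G) * py)
  sx <- sqrt(sum(((1:G) - mux)^2 * px)); sy <- sqrt(sum(((1:G) - muy)^2 * py))
  psum <- numeric(2 * G); pdiff <- numeric(G)
  for (i in 1:G) for (j in 1:G) {
    psum[i + j] <- psum[i + j] + P[i, j]
    pdiff[abs(i - j) + 1] <- pdiff[abs(i - j) + 1] + P[i, j]
  }
  H <- function(p) { s <- 0; for (v in p) if (v > 0) s <- s - v * log(v); s }
  f1 <- sum(P^2)
  f2 <- sum((0:(G - 1))^2 * pdiff)
  f3 <- 0
  if (sx > 0 && sy > 0) {
    acc <- 0
    for (i in 1:G) for (j in 1:G) acc <- acc + i * j * P[i, j]
    f3 <- (acc - mux * muy) / (sx * sy)
  }
  f4 <- 0; for (i in 1:G) for (j in 1:G) f4 <- f4 + (i - mux)^2 * P[i, j]
  f5 <- 0; for (i in 1:G) for (j in 1:G) f5 <- f5 + P[i, j] / (1 + (i - j)^2)
  f6 <- sum((2:(2 * G)) * psum[2:(2 * G)])
  f7 <- sum(((2:(2 * G)) - f6)^2 * psum[2:(2 * G)])
  f8 <- H(psum)
  f9 <- H(P)
  mud <- sum((0:(G - 1)) * pdiff)
  f10 <- sum(((0:(G - 1)) - mud)^2 * pdiff)
  f11 <- H(pdiff)
  hx <- H(px); hy <- H(py)
  hxy1 <- 0; hxy2 <- 0
  for (i in 1:G) for (j in 1:G) {
    if (px[i] * py[j] > 0) {
      if (P[i, j] > 0) hxy1 <- hxy1 - P[i, j] * log(px[i] * py[j])
      hxy2 <- hxy2 - px[i] * py[j] * log(px[i] * py[j])
    }
  }
  f12 <- if (max(hx, hy) > 0) (f9 - hxy1) / max(hx, hy) else 0
  f13 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - f9))))
  c(f1, f2, f3, f4, f5, f6, f7, f8, f9, f10, f11, f12, f13)
}

# oracle for the full pipeline step: average the 13 statistics over the four
# directions that produce at least one pair
oracleHaralickImage <- function(q, G) {
  offs <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))
  mats <- list()
  for (o in offs) {
    P <- oracleGLCM(q, o[1], o[2], G)
    if (!any(is.nan(P))) mats[[length(mats) + 1]] <- P
  }
  rowMeans(sapply(mats, oracleHaralick13))
}
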
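# Independent brute-force oracles, deliberately naive.

# Binary dilation by explicit neighbourhood union (clipped at bounds).
brute_dilate <- function(mask, radius, shape = "box") {
  fg <- mask > 0
  out <- matrix(FALSE, nrow(fg), ncol(fg))
  offs <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  if (shape == "diamond") offs <- offs[abs(offs$dr) + abs(offs$dc) <= radius, ]
  idx <- which(fg, arr.ind = TRUE)
  for (i in seq_len(nrow(offs))) {
    r <- idx[, 1] + offs$dr[i]
    c <- idx[, 2] + offs$dc[i]
    ok <- r >= 1 & r <= nrow(fg) & c >= 1 & c <= ncol(fg)
    out[cbind(r[ok], c[ok])] <- TRUE
  }
  out
}

# AUROC by exhaustive positive-negative pair counting, ties half credit.
brute_auroc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  wins <- outer(pos, neg, `>`) + 0.5 * outer(pos, neg, `==`)
  sum(wins) / (length(pos) * length(neg))
}

# Per-column foreground pixel count, axis-aligned (no rotation).
column_pixel_heights <- function(mask, fractions, halfwidth) {
  fg <- mask > 0
  cols <- which(colSums(fg) > 0)
  x0 <- min(cols)
  extent <- max(cols) - x0
  vapply(fractions, function(f) {
    ctr <- x0 + f * extent
    band <- cols[abs(cols - ctr) <= halfwidth * extent + 1e-9]
    sub <- fg[, band, drop = FALSE]
    rows <- which(rowSums(sub) > 0)
    max(rows) - min(rows) + 1
  }, numeric(1))
}

random_mask <- function(nr, nc, p = 0.3) {
  matrix(as.integer(stats::runif(nr * nc) < p), nr, nc)
}

# Small wedge phantom used across tests.
wedge_phantom <- function(target = 1 / 3, hp = 15, n = 1) {
  plan <- data.frame(vertebra = 1L, class = "wedge", target_hlr = target)
  generate_spine(phantom_spec(n, hp, deformity_plan = plan))
}
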
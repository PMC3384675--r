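# Independent oracles and fixture builders shared across test files.

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1L]] != strsplit(b, "")[[1L]])
}

# Brute-force circular spatial cross-correlation of scene s with object o
# (both real matrices of equal size): the plain double-loop definition,
# kept deliberately independent of any FFT.
brute_circular_xcorr <- function(s, o) {
  M <- nrow(s); N <- ncol(s)
  out <- matrix(0, M, N)
  for (dr in 0:(M - 1)) for (dc in 0:(N - 1)) {
    acc <- 0
    for (x in 0:(M - 1)) for (y in 0:(N - 1)) {
      acc <- acc + s[(x + dr) %% M + 1, (y + dc) %% N + 1] * o[x + 1, y + 1]
    }
    out[dr + 1, dc + 1] <- acc
  }
  out
}

# Exhaustive max scan with (row, col) lexicographic tie-break.
brute_peak <- function(v) {
  best <- NULL
  for (r in seq_len(nrow(v))) for (c in seq_len(ncol(v))) {
    if (is.null(best) || v[r, c] > best$intensity) {
      best <- list(intensity = v[r, c], row = r - 1L, col = c - 1L)
    }
  }
  best
}

# Exhaustive threshold search: evaluate every midpoint candidate plus
# +/-Inf directly, applying the Ex-then-Sp-then-threshold tie-break.
brute_calibrate <- function(intensity, truth) {
  u <- sort(unique(intensity))
  cand <- c(-Inf, (u[-length(u)] + u[-1]) / 2, Inf)
  score <- function(t) {
    pred <- intensity > t
    tp <- sum(pred & truth); tn <- sum(!pred & !truth)
    fp <- sum(pred & !truth); fn <- sum(!pred & truth)
    c(ex = (tp + tn) / length(truth), sp = tn / max(tn + fp, 1))
  }
  sc <- t(vapply(cand, score, c(ex = 0, sp = 0)))
  cand[order(-sc[, "ex"], -sc[, "sp"], -cand)[1L]]
}

# Embed `query` into a fresh random scene-sized database window at base
# `at` (0-based) and return the scene image.
scene_with_embedding <- function(query, at, width = 100, height = 100) {
  cap <- width * height
  stopifnot(at + nchar(query) <= cap)
  bg <- rand_seq(cap)
  db <- paste0(substr(bg, 1, at), query,
               substr(bg, at + nchar(query) + 1, cap))
  tile_database(db, width = width, height = height)[[1L]]
}
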
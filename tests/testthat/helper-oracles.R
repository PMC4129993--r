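# Independent brute-force oracles. These deliberately re-derive the features
# from their set definitions, materializing every pixel subset explicitly,
# and never share code with the package implementations they check.

bruteBTC <- function(block) {
  x <- as.numeric(block)
  mu <- sum(x) / length(x)
  high <- x[x >= mu]
  low <- x[x < mu]
  if (length(unique(x)) == 1L)
    return(c(mu, mu, mu, mu))
  muH <- sum(high) / length(high)
  muL <- sum(low) / length(low)
  if (length(unique(high)) == 1L) {
    ht <- muH; hb <- muH
  } else {
    topH <- high[high >= muH]
    botH <- high[high >= mu & high < muH]
    ht <- sum(topH) / length(topH)
    hb <- sum(botH) / length(botH)
  }
  if (length(unique(low)) == 1L) {
    lt <- muL; lb <- muL
  } else {
    topL <- low[low >= muL & low < mu]
    botL <- low[low < muL]
    lt <- sum(topL) / length(topL)
    lb <- sum(botL) / length(botL)
  }
  c(ht, hb, lt, lb)
}

# per-bit loop LBP: explicit trigonometry, own bilinear sampler
bruteLBP <- function(frame, x, y, P, R, beta) {
  H <- nrow(frame); W <- ncol(frame)
  sampleAt <- function(r, c) {
    r0 <- floor(r); c0 <- floor(c)
    fr <- r - r0; fc <- c - c0
    gv <- function(rr, cc)
      frame[min(max(rr, 1), H), min(max(cc, 1), W)]
    gv(r0, c0) * (1 - fr) * (1 - fc) + gv(r0, c0 + 1) * (1 - fr) * fc +
      gv(r0 + 1, c0) * fr * (1 - fc) + gv(r0 + 1, c0 + 1) * fr * fc
  }
  code <- 0
  for (p in 0:(P - 1)) {
    ang <- 2 * pi * p / P
    dx <- R * cos(ang); dy <- -R * sin(ang)
    if (P == 8 && R == 1) { dx <- round(dx + sign(dx) * 0.2); dy <- round(dy + sign(dy) * 0.2) }
    if (abs(dx - round(dx)) < 1e-9) dx <- round(dx)
    if (abs(dy - round(dy)) < 1e-9) dy <- round(dy)
    gp <- sampleAt(y + dy, x + dx)
    bit <- if (gp - frame[y, x] + beta >= 0) 1 else 0
    code <- code + bit * 2^p
  }
  code
}

randomBlock <- function(n = 8L, lo = 0, hi = 255) {
  matrix(round(runif(n * n, lo, hi)), n, n)
}
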
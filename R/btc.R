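#' Block truncation coding (BTC) intensity feature of a subblock
#'
#' Summarizes an intensity block by four conditional means obtained by
#' thresholding twice: first at the block mean `mu` (splitting pixels into a
#' high side `>= mu` and a low side `< mu` with means `mu_h`, `mu_l`), then
#' at `mu_h` within the high side and at `mu_l` within the low side:
#'
#' * `muHT`: mean of pixels `>= mu_h`
#' * `muHB`: mean of pixels in `[mu, mu_h)`
#' * `muLT`: mean of pixels in `[mu_l, mu)`
#' * `muLB`: mean of pixels `< mu_l`
#'
#' Degenerate blocks are handled explicitly: if all pixels are equal, all
#' four components are `mu`; if all high-side (low-side) pixels are equal,
#' both high (low) components are `mu_h` (`mu_l`). The components always
#' satisfy `muLB <= muLT <= mu <= muHB <= muHT`.
#'
#' @param block nonempty numeric matrix or vector of intensities
#' @return named numeric vector `c(muHT, muHB, muLT, muLB)` with attributes
#'   `mu`, `muH`, `muL` (the intermediate means) for diagnostics
#' @examples
#' btcFeature(matrix(c(10, 20, 30, 40), 2, 2))  # (40, 30, 20, 10)
#' btcFeature(matrix(7, 4, 4))                  # constant block: (7, 7, 7, 7)
#' @export
btcFeature <- function(block) {
  x <- as.numeric(block)
  if (length(x) == 0L) stop("empty block")
  mu <- mean(x)
  hi <- x[x >= mu]
  lo <- x[x < mu]
  if (length(lo) == 0L) {
    # all pixels identical (for non-constant data some pixel is < mean)
    v <- c(muHT = mu, muHB = mu, muLT = mu, muLB = mu)
    attr(v, "mu") <- mu; attr(v, "muH") <- mu; attr(v, "muL") <- mu
    return(v)
  }
  muH <- mean(hi)
  muL <- mean(lo)
  if (max(hi) == min(hi)) {
    muHT <- muH; muHB <- muH
  } else {
    muHT <- mean(hi[hi >= muH])
    muHB <- mean(hi[hi < muH])
  }
  if (max(lo) == min(lo)) {
    muLT <- muL; muLB <- muL
  } else {
    muLT <- mean(lo[lo >= muL])
    muLB <- mean(lo[lo < muL])
  }
  v <- c(muHT = muHT, muHB = muHB, muLT = muLT, muLB = muLB)
  attr(v, "mu") <- mu; attr(v, "muH") <- muH; attr(v, "muL") <- muL
  v
}

#' Intensity-structure similarity between two subblocks
#'
#' Normalized correlation of the mean-absolute-deviation profiles of two
#' blocks: with `U_X = (|mu_X - x_1|, ..., |mu_X - x_MN|)` over pixels in
#' raster order, `S = |U_A . U_B| / (||U_A|| ||U_B||)`. `S` lies in \[0, 1\]
#' by Cauchy-Schwarz and is invariant under adding a constant to all pixels
#' of a block, so it measures shared contrast structure, not brightness.
#' Degenerate blocks (a `U` of all zeros, i.e. constant): both constant gives
#' `S = 1`, exactly one constant gives `S = 0`.
#'
#' @param blockA,blockB numeric matrices of identical shape
#' @return similarity `S` in \[0, 1\]
#' @examples
#' a <- matrix(c(10, 20, 30, 40), 2, 2)
#' blockSimilarity(a, a)       # 1
#' blockSimilarity(a, a + 50)  # 1: additive shift leaves U unchanged
#' @export
blockSimilarity <- function(blockA, blockB) {
  if (!identical(dim(blockA), dim(blockB)) ||
      length(blockA) != length(blockB))
    stop("blocks must have the same shape")
  a <- as.numeric(blockA)
  b <- as.numeric(blockB)
  uA <- abs(mean(a) - a)
  uB <- abs(mean(b) - b)
  nA <- sqrt(sum(uA * uA))
  nB <- sqrt(sum(uB * uB))
  if (nA == 0 && nB == 0) return(1)
  if (nA == 0 || nB == 0) return(0)
  min(1, abs(sum(uA * uB)) / (nA * nB))
}
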
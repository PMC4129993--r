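#' Initialize the background model of one subblock
#'
#' From the first frame, each subblock gets a weighted set of K feature
#' vectors: entry 1 carries the observed BTC feature with weight 1, the
#' remaining K - 1 entries are zero-vector placeholders with weight 0 (they
#' can never match and exist only as replacement targets). The initializing
#' pixel block is kept as the subblock's background exemplar patch, used
#' later to compute the similarity S that modulates the distance threshold.
#'
#' @param firstFeature BTC feature vector from frame 1 (see [btcFeature()])
#' @param firstBlock the M x N intensity block it came from
#' @param cfg a [detectorConfig()]
#' @return a block-model record: list with elements `features` (4 x K
#'   matrix, columns weight-ordered), `weights` (sums to 1), `lastMatch`
#'   (frame of last match per entry, for weight-tie ordering), `exemplar`
#' @export
initBlockModel <- function(firstFeature, firstBlock, cfg) {
  K <- cfg$K
  features <- matrix(0, nrow = 4L, ncol = K)
  features[, 1L] <- as.numeric(firstFeature)[1:4]
  weights <- c(1, rep.int(0, K - 1L))
  list(features = features, weights = weights,
       lastMatch = c(1, rep.int(0, K - 1L)),
       exemplar = matrix(as.numeric(firstBlock), nrow(firstBlock), ncol(firstBlock)))
}

#' Number of model entries representing background
#'
#' With entries sorted by weight (nonincreasing), the first `B` entries whose
#' cumulative weight strictly exceeds the threshold `T` represent background;
#' the remaining `K - B` entries represent transient (object) appearances.
#'
#' @param weights numeric vector, nonincreasing, summing to 1
#' @param T background-weight threshold in (0, 1)
#' @return the count `B` (at least 1, at most `length(weights)`)
#' @examples
#' backgroundCount(c(0.6, 0.3, 0.1), 0.7)   # 2
#' backgroundCount(c(0.8, 0.15, 0.05), 0.7) # 1
#' @export
backgroundCount <- function(weights, T) {
  cs <- cumsum(weights)
  b <- which(cs > T)
  if (length(b) == 0L) length(weights) else b[1L]
}

#' Euclidean distance between two BTC feature vectors
#'
#' @param v,vk feature vectors of length 4
#' @return nonnegative distance
#' @export
featureDistance <- function(v, vk) {
  d <- as.numeric(v)[1:4] - as.numeric(vk)[1:4]
  sqrt(sum(d * d))
}

#' Similarity-adaptive distance threshold
#'
#' The matching threshold is scaled per subblock and per frame as
#' `T_D_eff = T_D_base * (alpha + S)` where `S` is the intensity-structure
#' similarity between the incoming block and the subblock's background
#' exemplar. The scaling is always applied to the constant base threshold,
#' never compounded across frames (a self-referential update would diverge
#' whenever `alpha + S > 1`). Blocks that still resemble the background
#' (S near 1) get a permissive threshold; blocks whose internal contrast
#' structure changed get a strict one.
#'
#' @param TDBase base distance threshold, intensity units
#' @param alpha empirical constant, conventionally in \[0.7, 0.8\]
#' @param S similarity in \[0, 1\] (see [blockSimilarity()])
#' @return effective threshold
#' @export
adaptiveThreshold <- function(TDBase, alpha, S) {
  TDBase * (alpha + S)
}

#' Classify one subblock and update its background model
#'
#' One coarse-stage step for a single subblock:
#' 1. Compute the incoming BTC feature `v` and the similarity `S` to the
#'    background exemplar; derive the effective threshold
#'    (see [adaptiveThreshold()]).
#' 2. Entries with feature distance below the threshold are match
#'    candidates; the closest wins (weight breaks ties).
#' 3. A match within the first `B` weight-sorted entries
#'    (see [backgroundCount()]) labels the block background; a match beyond
#'    them labels it object.
#' 4. No match: the minimum-weight entry is replaced by `(v, alpha_w)`,
#'    weights are renormalized, and the block is labeled object.
#' 5. On a match, all weights move by `w <- (1 - alpha_w) w + alpha_w M_k`
#'    (`M_k = 1` only for the matched entry) and are renormalized; the
#'    matched feature moves toward `v` at rate `alpha_b` only when the block
#'    was labeled background (the object region does not update the
#'    background description).
#' 6. The exemplar patch tracks the block at rate `alpha_b`, background
#'    labels only. Entries are re-sorted by weight (ties: most recently
#'    matched first).
#'
#' @param model a block-model record from [initBlockModel()]
#' @param block incoming M x N intensity block
#' @param cfg a [detectorConfig()]
#' @param frameIndex current frame ordinal (recency bookkeeping)
#' @return list with `label` ("background" or "object"), the updated
#'   `model`, and diagnostics `S`, `TDEff`, `distance` (NA when unmatched)
#' @export
classifyAndUpdate <- function(model, block, cfg, frameIndex = NA_integer_) {
  if (is.null(model$features)) stop("uninitialized block model")
  v <- btcFeature(block)
  S <- blockSimilarity(block, model$exemplar)
  TDEff <- adaptiveThreshold(cfg$TDBase, cfg$alpha, S)
  d <- sqrt(colSums((model$features - as.numeric(v)[1:4])^2))
  B <- backgroundCount(model$weights, cfg$T)
  cand <- which(d < TDEff)
  if (length(cand) == 0L) {
    # replacement: new appearance enters with the minimum weight
    worst <- which(model$weights == min(model$weights))
    worst <- worst[which.min(model$lastMatch[worst])]
    model$features[, worst] <- as.numeric(v)[1:4]
    model$weights[worst] <- cfg$alphaW
    model$weights <- model$weights / sum(model$weights)
    model$lastMatch[worst] <- frameIndex
    label <- "object"
    dist <- NA_real_
  } else {
    k <- cand[order(d[cand], -model$weights[cand])][1L]
    label <- if (k <= B) "background" else "object"
    dist <- d[k]
    M <- numeric(length(model$weights)); M[k] <- 1
    w <- (1 - cfg$alphaW) * model$weights + cfg$alphaW * M
    model$weights <- w / sum(w)
    if (label == "background")
      model$features[, k] <- (1 - cfg$alphaB) * model$features[, k] +
        cfg$alphaB * as.numeric(v)[1:4]
    model$lastMatch[k] <- frameIndex
  }
  if (label == "background")
    model$exemplar <- (1 - cfg$alphaB) * model$exemplar + cfg$alphaB * block
  ord <- order(-model$weights, -model$lastMatch)
  model$features <- model$features[, ord, drop = FALSE]
  model$weights <- model$weights[ord]
  model$lastMatch <- model$lastMatch[ord]
  list(label = label, model = model, S = S, TDEff = TDEff, distance = dist)
}
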
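#' Pair residues between two conformers of the same chain
#'
#' Matches residue rows on (chain, resseq, insert, resname). Residues
#' present in only one table — or present at the same position with a
#' different residue name — are excluded from the pairing and returned in
#' the \code{unmatched} attribute rather than silently dropped. Pairs are
#' ordered by chain and sequence position.
#'
#' @param a,b residue tables (\code{\link{residueTable}} output) of the
#'   two structures; side a is the reference.
#' @return data.frame: chain, resseq, insert, resname, osp_a, osp_b,
#'   diff (= osp_b - osp_a), with attribute \code{unmatched} (data.frame
#'   with a \code{side} column).
#' @export
pairResidues <- function(a, b) {
  ka <- paste(a$chain, a$resseq, a$insert, a$resname, sep = "|")
  kb <- paste(b$chain, b$resseq, b$insert, b$resname, sep = "|")
  common <- intersect(ka, kb)
  if (!length(common))
    stop(errorCondition("pairing error: no residues in common",
                        class = c("fibos_pairing_error", "error",
                                  "condition")))
  ia <- match(common, ka); ib <- match(common, kb)
  pairs <- data.frame(chain = a$chain[ia], resseq = a$resseq[ia],
                      insert = a$insert[ia], resname = a$resname[ia],
                      osp_a = a$osp[ia], osp_b = b$osp[ib],
                      stringsAsFactors = FALSE)
  pairs$diff <- pairs$osp_b - pairs$osp_a
  pairs <- pairs[order(pairs$chain, pairs$resseq, pairs$insert), ,
                 drop = FALSE]
  rownames(pairs) <- NULL
  un <- rbind(
    if (any(!(ka %in% common)))
      cbind(a[!(ka %in% common), c("chain", "resseq", "insert", "resname")],
            side = "a"),
    if (any(!(kb %in% common)))
      cbind(b[!(kb %in% common), c("chain", "resseq", "insert", "resname")],
            side = "b"))
  if (is.null(un))
    un <- data.frame(chain = character(), resseq = integer(),
                     insert = character(), resname = character(),
                     side = character())
  rownames(un) <- NULL
  attr(pairs, "unmatched") <- un
  pairs
}

#' Two-sided Wilcoxon signed-rank test on paired differences
#'
#' Zero differences are dropped (Wilcoxon's original convention) and ties
#' among the absolute values receive mid-ranks. For n <= 25 non-zero
#' differences the exact null distribution of the positive-rank sum is
#' used (computed by convolution over the doubled mid-ranks, which is
#' exact even under ties); above that, the normal approximation with tie
#' correction and continuity correction. The two-sided p-value is
#' 2 * min(P(W <= w), P(W >= w)), capped at 1. All differences zero gives
#' p = 1 by convention.
#'
#' @param diffs numeric paired differences.
#' @return list(statistic = positive-rank sum W, n = non-zero count,
#'   p.value).
#' @export
wilcoxonSignedRank <- function(diffs) {
  stopifnot(is.numeric(diffs))
  d <- diffs[diffs != 0]
  n <- length(d)
  if (!n) return(list(statistic = 0, n = 0L, p.value = 1))
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= 25) {
    r2 <- as.integer(round(2 * r))          # doubled mid-ranks: integers
    S <- sum(r2)
    f <- numeric(S + 1); f[1] <- 1
    for (rr in r2) {
      g <- f
      g[(rr + 1):(S + 1)] <- g[(rr + 1):(S + 1)] + f[1:(S + 1 - rr)]
      f <- g
    }
    w2 <- as.integer(round(2 * W))
    tot <- 2^n
    p_le <- sum(f[1:(w2 + 1)]) / tot
    p_ge <- sum(f[(w2 + 1):(S + 1)]) / tot
    p <- min(1, 2 * min(p_le, p_ge))
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    if (sig2 <= 0 || W == mu) return(list(statistic = W, n = n, p.value = 1))
    z <- (W - mu - 0.5 * sign(W - mu)) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(statistic = W, n = as.integer(n), p.value = p)
}

#' Paired Wilcoxon p-value and Cohen's d for residue pairs
#'
#' The paired effect size is Cohen's d for paired data,
#' d = mean(diff) / sd(diff). When every difference is zero the
#' convention is p = 1, d = 0.
#'
#' @param pairs output of \code{\link{pairResidues}} (or any data.frame
#'   with a \code{diff} column).
#' @return list(wilcoxon_p, cohens_d, n).
#' @export
pairedStats <- function(pairs) {
  d <- pairs$diff
  if (length(d) < 2) stop("domain error: need at least 2 pairs")
  if (all(d == 0))
    return(list(wilcoxon_p = 1, cohens_d = 0, n = length(d)))
  sdd <- stats::sd(d)
  cd <- if (sdd == 0) sign(mean(d)) * Inf else mean(d) / sdd
  list(wilcoxon_p = wilcoxonSignedRank(d)$p.value, cohens_d = cd,
       n = length(d))
}

.sideStat <- function(pairs, side) {
  switch(side,
         a = stats::sd(pairs$osp_a),
         b = stats::sd(pairs$osp_b),
         gap = stats::sd(pairs$osp_b) - stats::sd(pairs$osp_a))
}

#' Influence of each residue on the OSP dispersion (difference)
#'
#' Scores how much each paired residue contributes to the standard
#' deviation of residue OSP — of side a, side b, or their gap
#' sd(b) - sd(a) (default). The jackknife mode uses the empirical
#' influence: score_i = statistic on all pairs minus the statistic with
#' pair i removed, so a large positive score on side "gap" marks a
#' residue inflating the b-side excess dispersion. The analytic mode uses
#' the influence function of the standard deviation,
#' IF(x) = ((x - mu)^2 - sigma^2) / (2 sigma), scaled by 1/(n-1) to be
#' comparable with the jackknife scores.
#'
#' @param pairs output of \code{\link{pairResidues}} (>= 3 pairs).
#' @param side "gap" (default), "a" or "b".
#' @param mode "jackknife" (default) or "analytic".
#' @return numeric influence score per pair, in pair order.
#' @export
sdInfluence <- function(pairs, side = c("gap", "a", "b"),
                        mode = c("jackknife", "analytic")) {
  side <- match.arg(side)
  mode <- match.arg(mode)
  n <- nrow(pairs)
  if (n < 3) stop("domain error: need at least 3 pairs")
  if (mode == "jackknife") {
    full <- .sideStat(pairs, side)
    vapply(seq_len(n),
           function(i) full - .sideStat(pairs[-i, , drop = FALSE], side),
           numeric(1))
  } else {
    ifsd <- function(x) {
      s <- stats::sd(x)
      if (s == 0) return(rep(0, length(x)))
      ((x - mean(x))^2 - s^2) / (2 * s)
    }
    sc <- switch(side, a = ifsd(pairs$osp_a), b = ifsd(pairs$osp_b),
                 gap = ifsd(pairs$osp_b) - ifsd(pairs$osp_a))
    sc / (n - 1)
  }
}

#' Flag influential residues by a robust outlier rule
#'
#' A residue is flagged when its influence score exceeds
#' median(scores) + madK * MAD(scores) (MAD with the usual 1.4826
#' consistency constant). With all scores equal nothing is flagged; the
#' flagged set shrinks monotonically as madK grows.
#'
#' @param scores numeric influence scores (finite).
#' @param madK MAD multiplier (default 3).
#' @return logical vector, TRUE for flagged residues.
#' @export
flagInfluential <- function(scores, madK = 3) {
  stopifnot(all(is.finite(scores)), madK >= 0)
  scores > stats::median(scores) + madK * stats::mad(scores)
}

#' Paired packing comparison of two structures
#'
#' Runs \code{\link{packingDensity}} on both structures, pairs their
#' residues, and computes the paired comparison statistics: Wilcoxon
#' signed-rank p, paired Cohen's d, per-side residue-OSP mean and SD and
#' their gap, and the influence screening for residues driving the
#' dispersion difference.
#'
#' @param a,b \linkS4class{PDBStructure}s of the same chain, radii
#'   assigned (a is the reference, e.g. the experimental structure; b the
#'   model being compared).
#' @inheritParams occludedSurface
#' @param side dispersion attributed by the influence scores ("gap",
#'   "a" or "b").
#' @param madK MAD multiplier of the flagging rule.
#' @param mode influence estimator ("jackknife" or "analytic").
#' @param areaWeighted passed to \code{\link{residueTable}}.
#' @return a \linkS4class{ComparisonReport}.
#' @examples
#' pp <- makePerturbedPair(makeShell(1.7, 12), sigma = 0.05, seed = 7)
#' compareStructures(pp$a, pp$b, density = 2)
#' @export
compareStructures <- function(a, b, method = c("fibos", "os"),
                              density = 5.0, dW = 2.8,
                              side = c("gap", "a", "b"), madK = 3,
                              mode = c("jackknife", "analytic"),
                              areaWeighted = FALSE) {
  method <- match.arg(method); side <- match.arg(side)
  mode <- match.arg(mode)
  ra <- packingDensity(a, method = method, density = density, dW = dW,
                       areaWeighted = areaWeighted)$residues
  rb <- packingDensity(b, method = method, density = density, dW = dW,
                       areaWeighted = areaWeighted)$residues
  pairs <- pairResidues(ra, rb)
  st <- pairedStats(pairs)
  if (nrow(pairs) >= 3) {
    infl <- sdInfluence(pairs, side = side, mode = mode)
    pairs$influence <- infl
    pairs$flagged <- flagInfluential(infl, madK = madK)
  } else {
    # dispersion attribution is undefined below 3 pairs
    pairs$influence <- rep(NA_real_, nrow(pairs))
    pairs$flagged <- FALSE
  }
  new("ComparisonReport", pairs = pairs,
      unmatched = attr(pairs, "unmatched"),
      idA = structureId(a), idB = structureId(b),
      meanA = mean(pairs$osp_a), meanB = mean(pairs$osp_b),
      sdA = stats::sd(pairs$osp_a), sdB = stats::sd(pairs$osp_b),
      sdGap = stats::sd(pairs$osp_b) - stats::sd(pairs$osp_a),
      wilcoxonP = st$wilcoxon_p, cohensD = st$cohens_d,
      side = side, madK = madK)
}
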
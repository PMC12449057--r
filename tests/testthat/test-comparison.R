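res_table <- function(resseq, osp, resname = "ALA", chain = "A") {
  data.frame(chain = chain, resseq = resseq, insert = "",
             resname = rep(resname, length.out = length(resseq)),
             n_atoms = 1L, occluded_area = 1, mean_length = 1, osp = osp,
             stringsAsFactors = FALSE)
}

test_that("residue pairing matches identities and reports mismatches", {
  a <- res_table(1:3, c(0.1, 0.2, 0.3))
  p <- pairResidues(a, a)
  expect_equal(nrow(p), 3L)
  expect_equal(p$diff, rep(0, 3))

  b <- res_table(c(1, 3), c(0.15, 0.35))
  p2 <- pairResidues(a, b)
  expect_equal(nrow(p2), 2L)
  un <- attr(p2, "unmatched")
  expect_equal(un$resseq, 2)
  expect_equal(un$side, "a")

  # same position, different residue name: excluded and reported both sides
  c_ <- res_table(1:3, c(0.1, 0.2, 0.3), resname = c("ALA", "GLY", "ALA"))
  p3 <- pairResidues(a, c_)
  expect_equal(p3$resseq, c(1, 3))
  expect_equal(sort(attr(p3, "unmatched")$side), c("a", "b"))

  expect_error(pairResidues(a, res_table(11:13, c(0.1, 0.2, 0.3))),
               class = "fibos_pairing_error")
})

test_that("paired statistics: conventions and hand-computed values", {
  allz <- pairResidues(res_table(1:4, c(0.1, 0.2, 0.3, 0.4)),
                       res_table(1:4, c(0.1, 0.2, 0.3, 0.4)))
  st <- pairedStats(allz)
  expect_equal(st$wilcoxon_p, 1)
  expect_equal(st$cohens_d, 0)

  # diffs {1,2,3,4}: d = 2.5 / 1.290994...
  p <- data.frame(diff = c(1, 2, 3, 4))
  expect_equal(pairedStats(p)$cohens_d, 2.5 / sd(1:4), tolerance = 1e-9)
  expect_equal(pairedStats(p)$cohens_d, 1.9365, tolerance = 1e-4)

  # n = 6 all-positive diffs: exact two-sided p = 2/2^6
  p6 <- data.frame(diff = c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6))
  expect_equal(pairedStats(p6)$wilcoxon_p, 0.03125)
})

test_that("signed-rank p matches exhaustive sign-flip enumeration (n <= 10)", {
  set.seed(7)
  for (i in 1:40) {
    n <- sample(2:10, 1)
    d <- round(rnorm(n), 2)
    d[sample(n, sample(0:1, 1))] <- 0          # occasional zero diff
    expect_equal(wilcoxonSignedRank(d)$p.value, enum_wilcoxon_p(d),
                 tolerance = 1e-12, info = paste("case", i))
  }
})

test_that("signed-rank agrees with stats::wilcox.test on tie-free data", {
  set.seed(31)
  for (n in c(8, 15, 25)) {                    # exact regime
    d <- rnorm(n)
    expect_equal(wilcoxonSignedRank(d)$p.value,
                 suppressWarnings(wilcox.test(d)$p.value),
                 tolerance = 1e-10)
  }
  d <- rnorm(60)                               # normal-approximation regime
  expect_equal(wilcoxonSignedRank(d)$p.value,
               suppressWarnings(wilcox.test(d)$p.value),
               tolerance = 1e-6)
})

test_that("influence scores attribute dispersion to the right residues", {
  # identical sides: nothing to attribute
  eq <- pairResidues(res_table(1:6, seq(0.1, 0.6, 0.1)),
                     res_table(1:6, seq(0.1, 0.6, 0.1)))
  expect_equal(sdInfluence(eq), rep(0, 6))

  # one extreme osp_b outlier: maximum score, verified leave-one-out
  osp_a <- c(0.30, 0.32, 0.34, 0.36, 0.38, 0.40)
  osp_b <- osp_a; osp_b[4] <- 0.95
  pr <- pairResidues(res_table(1:6, osp_a), res_table(1:6, osp_b))
  sc <- sdInfluence(pr)
  expect_equal(which.max(sc), 4L)
  gap <- function(d) sd(d$osp_b) - sd(d$osp_a)
  expect_equal(sc[2], gap(pr) - gap(pr[-2, ]), tolerance = 1e-12)

  # nonzero sd gap implies nonzero total attribution
  expect_gt(sum(abs(sc)), 0)
  expect_error(sdInfluence(pr[1:2, ]), "domain error")

  # analytic influence mode ranks the planted outlier first too
  sca <- sdInfluence(pr, mode = "analytic")
  expect_equal(which.max(sca), 4L)
})

test_that("influence flagging is a robust outlier rule", {
  expect_equal(flagInfluential(rep(0.2, 30)), rep(FALSE, 30))

  set.seed(5)
  sc <- c(rnorm(50, 0, 0.01), 2)
  fl <- flagInfluential(sc)
  expect_equal(which(fl), 51L)

  expect_equal(sum(flagInfluential(sc, madK = 1e9)), 0)   # monotone limit
  expect_gte(sum(flagInfluential(sc, madK = 1)), sum(flagInfluential(sc, madK = 3)))
})

test_that("below three pairs the comparison runs with influence undefined", {
  s <- makeDimer(1.7, 3.2)
  rep_ <- compareStructures(s, s, density = 3)
  expect_equal(rep_@cohensD, 0)
  expect_equal(rep_@wilcoxonP, 1)
  pr <- pairedResidues(rep_)
  expect_true(all(is.na(pr$influence)))
  expect_equal(sum(pr$flagged), 0L)
})

test_that("swapping sides negates d and sd gap, keeps the p-value", {
  pp <- makePerturbedPair(makeLattice(k = 2), sigma = 0.08, seed = 3)
  r_ab <- compareStructures(pp$a, pp$b, density = 3)
  r_ba <- compareStructures(pp$b, pp$a, density = 3)
  expect_equal(r_ba@cohensD, -r_ab@cohensD, tolerance = 1e-9)
  expect_equal(r_ba@sdGap, -r_ab@sdGap, tolerance = 1e-9)
  expect_equal(r_ba@wilcoxonP, r_ab@wilcoxonP, tolerance = 1e-9)
})

test_that("dropping positively flagged residues narrows the dispersion gap", {
  base <- makeLattice()
  pp <- makePerturbedPair(base, sigma = 0, nOutliers = 1, seed = 2)
  rep_ <- compareStructures(pp$a, pp$b, density = 3)
  pr <- pairedResidues(rep_)
  stopifnot(any(pr$flagged), all(pr$influence[pr$flagged] > 0))
  gap_full <- abs(rep_@sdGap)
  keep <- pr[!pr$flagged, ]
  gap_trim <- abs(sd(keep$osp_b) - sd(keep$osp_a))
  expect_lte(gap_trim, gap_full)
})
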
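mk_events <- function(...) {
  # build a transformed event table from per-marker values; unlisted markers
  # default to strongly negative
  rows <- list(...)
  out <- as.data.frame(matrix(0.2, nrow = length(rows),
                              ncol = length(bcp_markers()),
                              dimnames = list(NULL, bcp_markers())))
  for (i in seq_along(rows))
    for (m in names(rows[[i]])) out[i, m] <- rows[[i]][[m]]
  out
}

test_that("arcsinh transform has its closed-form values and preserves order", {
  ev <- data.frame(matrix(0, 1, 10, dimnames = list(NULL, bcp_markers())))
  expect_equal(unlist(transform_intensities(ev)), setNames(rep(0, 10), bcp_markers()))
  ev$CD19 <- 150 * sinh(1)
  expect_equal(transform_intensities(ev)$CD19, 1)
  x <- data.frame(matrix(rnorm(50 * 10, sd = 500), 50, 10,
                         dimnames = list(NULL, bcp_markers())))
  tx <- transform_intensities(x)
  for (m in bcp_markers())
    expect_identical(order(x[[m]]), order(tx[[m]]))
  expect_error(transform_intensities(x[, -3]), "missing channel")
  expect_error(transform_intensities(x, cofactors = -1), "positive")
})

test_that("density-valley thresholds fall between well-separated modes", {
  set.seed(41)
  tab <- data.frame(CD19 = c(rnorm(2000, 0, 0.5), rnorm(2000, 4, 0.5)),
                    TdT = rnorm(4000, 0, 0.5))
  thr <- estimate_thresholds(tab, markers = "CD19")
  expect_gt(thr$cutoff, 1)
  expect_lt(thr$cutoff, 3)
  expect_identical(thr$provenance, "estimated")
  # configured override returned verbatim
  thr2 <- estimate_thresholds(tab, markers = "CD19",
                              overrides = c(CD19 = 2.34))
  expect_identical(thr2$cutoff, 2.34)
  expect_identical(thr2$provenance, "configured")
  # unimodal channel: error without a fallback, configured with one
  expect_error(estimate_thresholds(tab, markers = "TdT"), "unimodal")
  thr3 <- estimate_thresholds(tab, markers = "TdT", fallback = 1.8)
  expect_identical(thr3$cutoff, 1.8)
  expect_identical(thr3$provenance, "configured")
  expect_error(estimate_thresholds(tab[1:50, ], markers = "CD19"),
               "too few events")
})

test_that("stage classification follows the BCR-marker hierarchy", {
  pos <- 3.4
  tab <- mk_events(
    c(cyCD79a = pos, CD19 = pos, cyIgM = pos),                 # pre-BII
    c(cyCD79a = 0.2),                                          # non-B
    c(cyCD79a = pos, TdT = pos),                               # pro-B
    c(cyCD79a = pos, CD19 = pos),                              # pre-BI
    c(cyCD79a = pos, CD19 = pos, smIgM = pos, cyIgM = pos),    # immature
    c(cyCD79a = pos, CD19 = pos, smIgM = pos, IgD = pos),      # mature
    c(cyCD79a = pos))                                          # unclassified
  thr <- toy_thresholds(bcp_markers())
  stage <- classify_stage(tab, thr)
  expect_identical(as.character(stage),
                   c("pre-BII", "non-B", "pro-B", "pre-BI", "immature",
                     "mature", "non-B"))
  expect_identical(attr(stage, "unclassified_b_lineage"), 1L)
})

test_that("pre-B subdivision splits on CD34/TdT", {
  pos <- 3.4
  tab <- mk_events(
    c(cyCD79a = pos, CD19 = pos, CD34 = pos, TdT = pos),              # pre-BI pp
    c(cyCD79a = pos, CD19 = pos),                                     # pre-BI nn
    c(cyCD79a = pos, CD19 = pos, cyIgM = pos, CD34 = pos),            # pre-BII int
    c(cyCD79a = pos, CD19 = pos, smIgM = pos))                        # immature
  thr <- toy_thresholds(bcp_markers())
  stage <- classify_stage(tab, thr)
  # note: row 1 is CD19+ TdT+ but CD19+ takes it out of the pro-B gate
  expect_identical(as.character(stage[1]), "pre-BI")
  sub <- subdivide_preB(tab, stage, thr)
  expect_identical(sub, c("pp", "nn", "intermediate", "not-applicable"))
})

test_that("compartment composition excludes mature cells and sums to 100", {
  stage <- rep(c("pro-B", "pre-BI", "pre-BII", "immature", "mature", "non-B"),
               c(10, 20, 40, 30, 50, 7))
  comp <- compartment_composition(stage)
  expect_equal(unname(comp), c(10, 20, 40, 30))
  expect_equal(sum(comp), 100, tolerance = 1e-12)
  expect_equal(unname(compartment_composition(rep("pre-BI", 5))["pre-BI"]), 100)
  expect_error(compartment_composition(rep("mature", 10)), "no precursor")
})

test_that("gating is deterministic and partitions all events", {
  sim <- simulate_bm_sample(donor_profile("healthy"), 20000, "hc", seed = 811)
  g1 <- gate_sample(sim)
  g2 <- gate_sample(sim)
  expect_identical(g1$labels, g2$labels)
  expect_identical(nrow(g1$labels), nrow(sim$events))
  expect_true(all(g1$labels$stage %in% bcpflow:::BCP_STAGES))
  # subdivision only set inside pre-BI/pre-BII
  pre <- g1$labels$stage %in% c("pre-BI", "pre-BII")
  expect_true(all(g1$labels$subdivision[!pre] == "not-applicable"))
  expect_true(all(g1$labels$subdivision[pre] %in%
                    c("pp", "nn", "intermediate")))
})

test_that("gating recovers generator truth at default separation", {
  sim <- simulate_bm_sample(donor_profile("healthy"), 40000, "hc", seed = 812)
  g <- gate_sample(sim)
  canon <- sim$truth$true_stage != "transitioning"
  expect_gte(mean(g$labels$stage[canon] == sim$truth$true_stage[canon]), 0.98)
  # subdivision truth-recovery on canonically labelled pre-B cells
  pre <- canon & sim$truth$true_subdivision %in% c("pp", "nn") &
    g$labels$stage == sim$truth$true_stage
  expect_gte(mean(g$labels$subdivision[pre] ==
                    sim$truth$true_subdivision[pre]), 0.98)
})

test_that("RAG-deficient samples show essentially no cells past pre-BI", {
  sim <- simulate_bm_sample(donor_profile("rag_deficient"), 30000, "rag",
                            seed = 813)
  g <- gate_sample(sim)
  stage <- g$labels$stage
  bcp <- sum(stage %in% bcpflow:::BCP_PRECURSOR_STAGES)
  late <- sum(stage %in% c("pre-BII", "immature", "mature"))
  expect_lt(late / bcp, 0.01)
})
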
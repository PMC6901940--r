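# Sub-stage marker location table, on the arcsinh-transformed scale.
# Levels: negative 0.25, dim 1.8, positive 3.4; within-population SD 0.4,
# so positive and negative staining modes sit ~7.9 SD apart by default.
# Sub-stages model the CD34/TdT heterogeneity inside pre-BI and pre-BII:
# pre-BI is mostly CD34+TdT+ (pp) with a CD34-TdT- minority (nn) that has
# begun to upregulate CD20; pre-BII is the reverse.
bm_level <- c(neg = 0.25, dim = 1.8, pos = 3.4)

bm_substage_locations <- function() {
  L <- bm_level
  m <- rbind(
    #          CD20     smIgM    CD38     TdT      cyCD79a  IgD      cyIgM    CD19     CD34     CD10
    non_B     = c(L["neg"], L["neg"], L["dim"], L["neg"], L["neg"], L["neg"], L["neg"], L["neg"], L["neg"], L["neg"]),
    proB      = c(L["neg"], L["neg"], L["pos"], L["pos"], L["pos"], L["neg"], L["neg"], L["neg"], L["pos"], L["pos"]),
    preBI_pp  = c(L["neg"], L["neg"], L["pos"], L["pos"], L["pos"], L["neg"], L["neg"], L["pos"], L["pos"], L["pos"]),
    preBI_nn  = c(L["dim"], L["neg"], L["pos"], L["neg"], L["pos"], L["neg"], L["neg"], L["pos"], L["neg"], L["pos"]),
    preBII_nn = c(L["dim"], L["neg"], L["pos"], L["neg"], L["pos"], L["neg"], L["pos"], L["pos"], L["neg"], L["pos"]),
    preBII_pp = c(L["neg"], L["neg"], L["pos"], L["pos"], L["pos"], L["neg"], L["pos"], L["pos"], L["pos"], L["pos"]),
    immature  = c(L["pos"], L["pos"], L["pos"], L["neg"], L["pos"], L["neg"], L["pos"], L["pos"], L["neg"], L["dim"]),
    mature    = c(L["pos"], L["pos"], L["dim"], L["neg"], L["pos"], L["pos"], L["pos"], L["pos"], L["neg"], L["neg"]))
  colnames(m) <- BCP_MARKERS
  m
}

bm_substage_stage <- c(non_B = "non-B", proB = "pro-B",
                       preBI_pp = "pre-BI", preBI_nn = "pre-BI",
                       preBII_nn = "pre-BII", preBII_pp = "pre-BII",
                       immature = "immature", mature = "mature")
bm_substage_subdiv <- c(non_B = "not-applicable", proB = "not-applicable",
                        preBI_pp = "pp", preBI_nn = "nn",
                        preBII_nn = "nn", preBII_pp = "pp",
                        immature = "not-applicable", mature = "not-applicable")

#' Donor profile for the bone-marrow cytometry simulator
#'
#' Bundles the stage mixture, marker location/scale model, transitioning-cell
#' fraction and donor-level shift scale for one donor type.
#'
#' * `healthy`: all stages present, pre-BI/pre-BII dominated respectively by
#'   CD34+TdT+ and CD34-TdT- cells with small asynchronous minorities.
#' * `rag_deficient`: V(D)J recombination blocked; zero weight on every
#'   cyIgM-positive stage (pre-BII, immature, mature) and no transitioning
#'   cells.
#' * `btk_deficient`: impaired pre-BCR signalling; a small but nonzero
#'   pre-BII fraction and near-zero immature/mature weight.
#'
#' @param name `"healthy"`, `"rag_deficient"` or `"btk_deficient"`.
#' @param transitioning_frac Fraction of BCP emitted as transitioning cells
#'   drawn along the segment joining the pre-BI and pre-BII centroids in
#'   transformed marker space. Default 0.02 (0 for `rag_deficient`, which has
#'   no pre-BII centroid to transit towards).
#' @param donor_shift_sd Donor-level per-marker mean shift, as a fraction of
#'   the within-population SD. Default 0.3.
#' @param nonb_frac Fraction of cyCD79a-negative non-B contaminant events.
#'   Default 0.08.
#' @param marker_sd Within-population SD on the transformed scale. Default 0.4.
#' @param cofactor arcsinh cofactor used to invert the transform back to raw
#'   fluorescence units. Default 150.
#' @return A list of class `donor_profile`.
#' @export
donor_profile <- function(name = c("healthy", "rag_deficient", "btk_deficient"),
                          transitioning_frac = NULL,
                          donor_shift_sd = 0.3,
                          nonb_frac = 0.08,
                          marker_sd = 0.4,
                          cofactor = 150) {
  name <- match.arg(name)
  weights <- switch(name,
    healthy = c(proB = 0.05, preBI_pp = 0.17, preBI_nn = 0.03,
                preBII_nn = 0.30, preBII_pp = 0.05,
                immature = 0.25, mature = 0.15),
    rag_deficient = c(proB = 0.30, preBI_pp = 0.55, preBI_nn = 0.15,
                      preBII_nn = 0, preBII_pp = 0,
                      immature = 0, mature = 0),
    btk_deficient = c(proB = 0.10, preBI_pp = 0.67, preBI_nn = 0.14,
                      preBII_nn = 0.06, preBII_pp = 0.02,
                      immature = 0.005, mature = 0.005))
  if (is.null(transitioning_frac))
    transitioning_frac <- if (name == "rag_deficient") 0 else 0.02
  stopifnot(abs(sum(weights) - 1) < 1e-9,
            transitioning_frac >= 0, transitioning_frac < 1,
            nonb_frac >= 0, nonb_frac < 1, marker_sd > 0, cofactor > 0)
  structure(list(name = name, weights = weights,
                 transitioning_frac = transitioning_frac,
                 donor_shift_sd = donor_shift_sd,
                 nonb_frac = nonb_frac, marker_sd = marker_sd,
                 cofactor = cofactor,
                 locations = bm_substage_locations()),
            class = "donor_profile")
}

#' Simulate a bone-marrow cytometry sample
#'
#' Draws per-cell 10-marker raw intensities for one donor. Cells are sampled
#' from per-sub-stage Gaussians on the arcsinh-transformed scale, a shared
#' donor-level mean shift is applied to all populations, transitioning cells
#' are placed uniformly along the segment between the canonical pre-BI
#' (CD34+TdT+) and pre-BII (CD34-TdT-) centroids, non-B (cyCD79a-negative)
#' contaminants are included, and intensities are mapped back to the raw
#' scale by inverting the arcsinh transform.
#'
#' @param profile A [donor_profile()].
#' @param n_cells Number of events (>= 1).
#' @param donor_id Donor identifier string.
#' @param seed Optional integer seed.
#' @return A list of class `bm_sample` with `events` (data frame: `cell_id`,
#'   `donor_id`, 10 raw marker columns) and `truth` (data frame: `cell_id`,
#'   `true_stage` in non-B/pro-B/pre-BI/pre-BII/immature/mature/transitioning,
#'   `true_subdivision` in pp/nn/not-applicable).
#' @export
simulate_bm_sample <- function(profile, n_cells, donor_id = "donor1",
                               seed = NULL) {
  if (!inherits(profile, "donor_profile")) stop("invalid profile")
  stopifnot(n_cells >= 1)
  if (!is.null(seed)) set.seed(seed)
  n_cells <- as.integer(n_cells)

  w <- profile$weights * (1 - profile$nonb_frac)
  p_bcp <- sum(w[c("proB", "preBI_pp", "preBI_nn", "preBII_nn", "preBII_pp",
                   "immature")])
  p_trans <- profile$transitioning_frac * p_bcp
  if (p_trans > 0) {
    preb <- c("preBI_pp", "preBI_nn", "preBII_nn", "preBII_pp")
    w[preb] <- w[preb] * (1 - p_trans / sum(w[preb]))
  }
  probs <- c(non_B = profile$nonb_frac, w, transitioning = p_trans)
  cats <- names(probs)
  idx <- sample.int(length(probs), n_cells, replace = TRUE, prob = probs)
  cat_of <- cats[idx]

  nm <- length(BCP_MARKERS)
  shift <- rnorm(nm, 0, profile$donor_shift_sd * profile$marker_sd)
  locs <- sweep(profile$locations, 2L, shift, `+`)
  mu <- locs[ifelse(cat_of == "transitioning", "preBI_pp", cat_of), ,
             drop = FALSE]
  is_tr <- cat_of == "transitioning"
  if (any(is_tr)) {
    u <- runif(sum(is_tr))
    mu[is_tr, ] <- (1 - u) * locs[rep("preBI_pp", sum(is_tr)), ] +
      u * locs[rep("preBII_nn", sum(is_tr)), ]
  }
  tvals <- mu + matrix(rnorm(n_cells * nm, 0, profile$marker_sd),
                       n_cells, nm)
  raw <- sinh(tvals) * profile$cofactor
  colnames(raw) <- BCP_MARKERS

  cell_id <- sprintf("%s_c%07d", donor_id, seq_len(n_cells))
  events <- data.frame(cell_id = cell_id, donor_id = donor_id,
                       raw, stringsAsFactors = FALSE, check.names = FALSE)
  true_stage <- ifelse(is_tr, "transitioning", bm_substage_stage[cat_of])
  true_sub <- ifelse(is_tr, "not-applicable", bm_substage_subdiv[cat_of])
  truth <- data.frame(cell_id = cell_id, true_stage = unname(true_stage),
                      true_subdivision = unname(true_sub),
                      stringsAsFactors = FALSE)
  structure(list(events = events, truth = truth, profile = profile,
                 donor_id = donor_id, donor_shift = shift),
            class = "bm_sample")
}
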
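REF_POPULATIONS <- c("pro-B", "pre-BI", "pre-BII", "immature")

#' Build a pooled-control principal-component reference model
#'
#' Pools the gated BCP events (pro-B, pre-BI, pre-BII, immature; non-B and
#' mature excluded) of two or more healthy control samples on the transformed
#' scale, standardizes each marker with the pooled mean and SD, and fits a
#' two-component PCA (the automated population separator view). For each
#' reference population, the mean and 2x2 covariance of its events in
#' PC1-PC2 define an elliptical contour at Mahalanobis distance `k`
#' ("`k` SD"); composition reference intervals are the min-max of the
#' per-control compartment compositions. PC1 is oriented so the immature
#' population mean is positive.
#'
#' @param gated List of >= 2 `bcp_gating` objects (see [gate_sample()]).
#' @param markers Markers fed to the PCA; default all 10 panel markers.
#' @param k Contour scale in Mahalanobis SD units. Default 2.
#' @param cofactors arcsinh cofactor(s) recorded for projecting new samples.
#' @param min_events Minimum pooled events required per reference population.
#' @return A list of class `bcp_reference`: `markers`, `center`/`scale`
#'   (pooled standardization), `loadings` (markers x 2, orthonormal),
#'   `sdev` (PC standard deviations), `populations` (per-population list
#'   with `mean` and `cov` in PC space), `k`, `composition_range` (2 x 4
#'   matrix of min/max percentages) and `cofactors`.
#' @export
build_reference <- function(gated, markers = bcp_markers(), k = 2,
                            cofactors = 150, min_events = 50L) {
  if (length(gated) < 2L) stop("need at least 2 gated control samples")
  pooled <- do.call(rbind, lapply(gated, function(g) {
    keep <- g$labels$stage %in% REF_POPULATIONS
    cbind(g$transformed[keep, markers, drop = FALSE],
          .stage = g$labels$stage[keep])
  }))
  x <- as.matrix(pooled[, markers])
  stage <- pooled$.stage
  for (p in REF_POPULATIONS)
    if (sum(stage == p) < min_events)
      stop("reference population ", p, " has fewer than ", min_events,
           " pooled events")
  ctr <- colMeans(x)
  scl <- apply(x, 2L, stats::sd)
  if (any(scl == 0)) stop("zero pooled SD for marker(s): ",
                          paste(markers[scl == 0], collapse = ", "))
  z <- sweep(sweep(x, 2L, ctr), 2L, scl, `/`)
  pc <- prcomp(z, center = FALSE, scale. = FALSE, rank. = 2L)
  load <- pc$rotation[, 1:2, drop = FALSE]
  scores <- z %*% load
  # sign convention: immature mean positive on PC1; largest |loading|
  # positive on PC2
  if (mean(scores[stage == "immature", 1L]) < 0) load[, 1L] <- -load[, 1L]
  if (load[which.max(abs(load[, 2L])), 2L] < 0) load[, 2L] <- -load[, 2L]
  scores <- z %*% load
  pops <- lapply(REF_POPULATIONS, function(p) {
    s <- scores[stage == p, , drop = FALSE]
    list(mean = colMeans(s), cov = stats::cov(s))
  })
  names(pops) <- REF_POPULATIONS
  comp <- vapply(gated, function(g) compartment_composition(g$labels$stage),
                 numeric(4L))
  rng <- rbind(min = apply(comp, 1L, min), max = apply(comp, 1L, max))
  structure(list(markers = markers, center = ctr, scale = scl,
                 loadings = load, sdev = pc$sdev[1:2],
                 populations = pops, k = k,
                 composition_range = rng, cofactors = cofactors,
                 n_controls = length(gated),
                 schema_version = BCPFLOW_SCHEMA),
            class = "bcp_reference")
}

#' Project events into the reference PC space
#'
#' Standardizes with the model's (not the sample's) pooled means and SDs and
#' applies the model loadings. Raw event tables are arcsinh-transformed with
#' the model's cofactors first; `bcp_gating` objects and already-transformed
#' tables are projected as-is.
#'
#' @param x A `bcp_gating` object, a raw event data frame, or a transformed
#'   event data frame (`transformed = TRUE`).
#' @param model A `bcp_reference`.
#' @param transformed Set `TRUE` when `x` is already on the transformed
#'   scale. Default `FALSE` for data frames.
#' @return Numeric matrix (events x 2) of PC1/PC2 coordinates.
#' @export
project_events <- function(x, model, transformed = FALSE) {
  if (inherits(x, "bcp_gating")) {
    tab <- x$transformed
  } else if (inherits(x, "bm_sample")) {
    tab <- transform_intensities(x$events, cofactors = model$cofactors,
                                 markers = model$markers)
  } else if (transformed) {
    tab <- x
  } else {
    tab <- transform_intensities(x, cofactors = model$cofactors,
                                 markers = model$markers)
  }
  missing <- setdiff(model$markers, names(tab))
  if (length(missing))
    stop("missing marker(s): ", paste(missing, collapse = ", "))
  z <- sweep(sweep(as.matrix(tab[, model$markers, drop = FALSE]),
                   2L, model$center), 2L, model$scale, `/`)
  z %*% model$loadings
}

# squared Mahalanobis distance of PC coordinates to one reference population
pop_dist2 <- function(scores, pop) {
  mahalanobis(scores, center = pop$mean, cov = pop$cov)
}

#' Fraction of BCP events outside the listed population contours
#'
#' Numerator: events gated into any of `populations` whose Mahalanobis
#' distance in PC space exceeds `k` for every listed population (with the
#' default, cells neither within the pre-BI nor the pre-BII 2SD contour).
#' Denominator: all BCP events (pro-B + pre-BI + pre-BII + immature).
#'
#' @param gated A `bcp_gating` object for the test sample.
#' @param model A `bcp_reference`.
#' @param populations Reference populations whose contours are tested.
#'   Default pre-BI and pre-BII.
#' @param k Contour scale; defaults to the model's `k`.
#' @return A single fraction in \[0, 1\].
#' @export
outside_fraction <- function(gated, model,
                             populations = c("pre-BI", "pre-BII"),
                             k = model$k) {
  stopifnot(all(populations %in% names(model$populations)))
  stage <- gated$labels$stage
  n_bcp <- sum(stage %in% BCP_PRECURSOR_STAGES)
  if (n_bcp == 0L) stop("no BCP events in sample")
  sel <- stage %in% populations
  if (!any(sel)) return(0)
  scores <- project_events(gated, model)[sel, , drop = FALSE]
  outside_all <- rep(TRUE, nrow(scores))
  for (p in populations)
    outside_all <- outside_all &
      (pop_dist2(scores, model$populations[[p]]) > k^2)
  sum(outside_all) / n_bcp
}

#' Compare a sample against the reference model
#'
#' Produces the per-sample deviation report: compartment composition versus
#' the reference intervals, per-population contour containment, the fraction
#' of BCP outside both the pre-BI and pre-BII contours, and a maturation
#' blockade call. The blockade rule operates on the measured composition:
#' `complete_block_preBI` when pre-BII plus immature make up less than 2% of
#' BCP (the RAG-deficiency pattern), `partial_block_preBII` when pre-BII
#' reaches 2% but immature stays below 2% (the BTK-deficiency pattern),
#' otherwise `none`.
#'
#' @param gated A `bcp_gating` object for the test sample.
#' @param model A `bcp_reference`.
#' @param range_margin Composition tolerance, in percentage points, added to
#'   the reference min-max intervals when flagging out-of-range stages
#'   (min-max over a handful of controls has no coverage guarantee, so a
#'   small margin absorbs counting noise). Default 2.
#' @return A list of class `deviation_report`: `composition` (data frame with
#'   per-stage percentage, reference range and in-range flag),
#'   `inside_own_contour` (named fractions), `outside_both`, `blockade` and
#'   `qc`.
#' @export
deviation_report <- function(gated, model, range_margin = 2) {
  comp <- compartment_composition(gated$labels$stage)
  rng <- model$composition_range
  in_range <- comp >= rng["min", ] - range_margin &
    comp <= rng["max", ] + range_margin
  scores <- project_events(gated, model)
  stage <- gated$labels$stage
  inside_own <- vapply(REF_POPULATIONS, function(p) {
    sel <- stage == p
    if (!any(sel)) return(NA_real_)
    d2 <- pop_dist2(scores[sel, , drop = FALSE], model$populations[[p]])
    mean(d2 <= model$k^2)
  }, 0)
  outside <- outside_fraction(gated, model)
  p_b2 <- comp[["pre-BII"]]; p_imm <- comp[["immature"]]
  blockade <- if (p_b2 + p_imm < 2) "complete_block_preBI"
              else if (p_b2 >= 2 && p_imm < 2) "partial_block_preBII"
              else "none"
  structure(list(
    composition = data.frame(stage = BCP_PRECURSOR_STAGES,
                             percent = unname(comp),
                             ref_min = unname(rng["min", ]),
                             ref_max = unname(rng["max", ]),
                             in_range = unname(in_range),
                             stringsAsFactors = FALSE),
    inside_own_contour = inside_own,
    outside_both = outside,
    blockade = blockade,
    k = model$k,
    qc = gated$qc,
    schema_version = BCPFLOW_SCHEMA),
    class = "deviation_report")
}

#' @export
print.deviation_report <- function(x, ...) {
  cat(render_report(x), sep = "\n")
  invisible(x)
}

#' Save a reference model as JSON
#'
#' @param model A `bcp_reference`.
#' @param path Output path. The file round-trips bit-exactly: reloading it
#'   with [ref_read()] reproduces identical projections.
#' @return Invisibly, `path`.
#' @export
ref_write <- function(model, path) {
  obj <- list(schema_version = model$schema_version,
              markers = model$markers,
              center = as.list(model$center),
              scale = as.list(model$scale),
              loadings = apply(model$loadings, 2L, as.list),
              sdev = model$sdev,
              populations = lapply(model$populations, function(p)
                list(mean = p$mean, cov = as.vector(p$cov))),
              k = model$k,
              composition_range = list(min = rng_list(model, "min"),
                                       max = rng_list(model, "max")),
              cofactors = model$cofactors,
              n_controls = model$n_controls)
  write_json_atomic(obj, path)
  invisible(path)
}

rng_list <- function(model, which)
  as.list(setNames(model$composition_range[which, ], REF_POPULATIONS))

#' Load a reference model saved by [ref_write()]
#'
#' @param path JSON path.
#' @return A `bcp_reference`.
#' @export
ref_read <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema_version, BCPFLOW_SCHEMA))
    stop("unsupported schema version: ", obj$schema_version)
  markers <- obj$markers
  # jsonlite only simplifies arrays; dict-valued fields come back as named
  # lists and need explicit flattening
  load <- matrix(c(unlist(obj$loadings$PC1), unlist(obj$loadings$PC2)),
                 ncol = 2L, dimnames = list(markers, c("PC1", "PC2")))
  pops <- lapply(obj$populations, function(p)
    list(mean = setNames(unlist(p$mean), c("PC1", "PC2")),
         cov = matrix(unlist(p$cov), 2L, 2L,
                      dimnames = list(c("PC1", "PC2"), c("PC1", "PC2")))))
  rng <- rbind(min = unlist(obj$composition_range$min),
               max = unlist(obj$composition_range$max))
  colnames(rng) <- REF_POPULATIONS
  structure(list(markers = markers,
                 center = setNames(unlist(obj$center), markers),
                 scale = setNames(unlist(obj$scale), markers),
                 loadings = load, sdev = obj$sdev,
                 populations = pops[REF_POPULATIONS], k = obj$k,
                 composition_range = rng, cofactors = obj$cofactors,
                 n_controls = obj$n_controls,
                 schema_version = obj$schema_version),
            class = "bcp_reference")
}
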
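# Independent oracles used across the suite. These deliberately avoid the
# package's own alignment/classification code paths.

# codon-by-codon translation using the standard genetic code
oracle_translate <- function(seq, from0, to0 = nchar(seq)) {
  starts <- seq.int(from0 + 1L, by = 3L, length.out = (to0 - from0) %/% 3L)
  if (!length(starts)) return("")
  codons <- substring(seq, starts, starts + 2L)
  paste(Biostrings::GENETIC_CODE[codons], collapse = "")
}

# frame/stop/productivity oracle: translate from the V reading-frame origin
# through the end of the J-Trp anchor codon
oracle_productivity <- function(seq, origin0, jtrp0) {
  in_frame <- (jtrp0 - origin0) %% 3L == 0L
  aa <- oracle_translate(seq, origin0, jtrp0 + 3L)
  has_stop <- grepl("*", aa, fixed = TRUE)
  list(frame = if (in_frame) "in-frame" else "out-of-frame",
       stop = has_stop,
       productivity = if (!in_frame) "unproductive_out_of_frame"
                      else if (has_stop) "unproductive_stop" else "in_frame")
}

# J-Trp anchor position (0-based, query coordinates) recomputed from the
# generator's truth fields by junction arithmetic
oracle_jtrp <- function(db, truth) {
  vi <- match(truth$v_name, db$V$name)
  di <- match(truth$d_name, db$D$name)
  ji <- match(truth$j_name, db$J$name)
  vlen <- nchar(db$V$seq)[vi] - truth$del_v
  dlen <- pmax(nchar(db$D$seq)[di] - truth$del_d5 - truth$del_d3, 0L)
  vlen + nchar(truth$n1) + dlen + nchar(truth$n2) +
    (db$J$trp_offset[ji] - truth$del_j)
}

oracle_frame_origin <- function(db, truth) {
  db$V$frame_offset[match(truth$v_name, db$V$name)]
}

# plain mean silhouette width on a distance matrix (small n only)
oracle_silhouette <- function(x, labels) {
  d <- as.matrix(dist(x))
  labels <- as.character(labels)
  widths <- vapply(seq_len(nrow(x)), function(i) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_len(nrow(x)) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(d[i, labels == l]), 0))
    (b - a) / max(a, b)
  }, 0)
  mean(widths)
}

# build a synthetic two-marker reference model directly (for contour-geometry
# properties that need exact control over the population distribution)
toy_reference <- function(scores, k = 2) {
  structure(list(
    markers = c("m1", "m2"),
    center = c(m1 = 0, m2 = 0), scale = c(m1 = 1, m2 = 1),
    loadings = matrix(c(1, 0, 0, 1), 2,
                      dimnames = list(c("m1", "m2"), c("PC1", "PC2"))),
    sdev = c(1, 1),
    populations = list(`pre-BI` = list(mean = colMeans(scores),
                                       cov = stats::cov(scores))),
    k = k,
    composition_range = NULL, cofactors = 150, n_controls = 1,
    schema_version = "1.0"), class = "bcp_reference")
}

toy_gating <- function(tab, stage) {
  structure(list(labels = data.frame(cell_id = seq_len(nrow(tab)),
                                     stage = stage,
                                     subdivision = "not-applicable",
                                     stringsAsFactors = FALSE),
                 thresholds = NULL, transformed = tab,
                 qc = list(unclassified_b_lineage = 0L)),
            class = "bcp_gating")
}

# constant threshold set for hand-constructed gating tables
toy_thresholds <- function(markers, cutoff = 1.8) {
  structure(data.frame(marker = markers, cutoff = cutoff,
                       provenance = "configured",
                       stringsAsFactors = FALSE),
            class = c("threshold_set", "data.frame"))
}
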
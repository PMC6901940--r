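#' Default repertoire configuration for a sorted pre-B compartment
#'
#' Junction-sampling parameters for the four sorted pre-B compartments
#' (CD34/TdT double-positive and double-negative subsets of pre-BI and
#' pre-BII). The default in-frame clone fractions are the calibration targets
#' of the generator: 0.10 for pre-BI+/+, 0.75 for pre-BI-/-, 0.80 for
#' pre-BII-/- and 0.75 for pre-BII+/+. The pre-BI-/- compartment uses a lower
#' mean junctional deletion count than the other three, which lengthens its
#' CDR3s.
#'
#' @param compartment One of `"preBI_pp"`, `"preBI_nn"`, `"preBII_nn"`,
#'   `"preBII_pp"`.
#' @param inframe_target Target marginal probability that a simulated clone is
#'   productive (in-frame without stop codon). Default per compartment as
#'   above.
#' @param del_mean Mean of the truncated-geometric deletion count applied
#'   independently at each junction end (V 3', D 5', D 3', J 5'), in
#'   nucleotides. Default 1.0 for `preBI_nn`, 2.5 otherwise.
#' @param n1_mean,n2_mean Poisson means of the untemplated (TdT) N1/N2
#'   insertion lengths, in nucleotides. Defaults 6 and 5 for all compartments
#'   so junction base composition is compartment-independent.
#' @param dup_prob Probability that a clone is emitted with duplicate reads
#'   (1 to 3 extra copies), exercising clone collapsing. Default 0.15.
#' @param max_attempts Rejection-sampling cap per clone; exceeded caps signal
#'   an infeasible configuration. Default 10000.
#' @return A list of class `compartment_config`.
#' @export
compartment_config <- function(compartment,
                               inframe_target = NULL,
                               del_mean = NULL,
                               n1_mean = 6,
                               n2_mean = 5,
                               dup_prob = 0.15,
                               max_attempts = 10000L) {
  compartment <- match.arg(compartment, BCP_COMPARTMENTS)
  defaults <- c(preBI_pp = 0.10, preBI_nn = 0.75,
                preBII_nn = 0.80, preBII_pp = 0.75)
  if (is.null(inframe_target)) inframe_target <- unname(defaults[compartment])
  if (is.null(del_mean)) del_mean <- if (compartment == "preBI_nn") 1.0 else 2.5
  stopifnot(inframe_target >= 0, inframe_target <= 1,
            del_mean >= 0, n1_mean >= 0, n2_mean >= 0)
  structure(list(compartment = compartment,
                 inframe_target = inframe_target,
                 del_mean = del_mean,
                 n1_mean = n1_mean, n2_mean = n2_mean,
                 dup_prob = dup_prob,
                 max_attempts = as.integer(max_attempts)),
            class = "compartment_config")
}

# geometric deletion count truncated at `cap`
rtrunc_geom <- function(n, mean, cap) {
  if (mean <= 0) return(integer(n))
  pmin(rgeom(n, prob = 1 / (1 + mean)), cap)
}

rand_nt <- function(len) {
  if (len == 0L) return("")
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# One junction draw (no class conditioning); returns assembled sequence plus
# the recomputed truth of the assembly.
draw_rearrangement <- function(db, cfg) {
  vi <- sample.int(nrow(db$V), 1L)
  di <- sample.int(nrow(db$D), 1L)
  ji <- sample.int(nrow(db$J), 1L)
  vseq <- db$V$seq[vi]; dseq <- db$D$seq[di]; jseq <- db$J$seq[ji]
  lv <- nchar(vseq); ld <- nchar(dseq)
  # anchors must survive trimming: V deletions limited to the tail after the
  # Cys codon, J deletions to the region 5' of the Trp codon
  v_cap <- lv - (db$V$cys_offset[vi] + 3L)
  j_cap <- db$J$trp_offset[ji]
  del_v <- rtrunc_geom(1L, cfg$del_mean, v_cap)
  del_d5 <- rtrunc_geom(1L, cfg$del_mean, ld)
  del_d3 <- rtrunc_geom(1L, cfg$del_mean, ld - del_d5)
  del_j <- rtrunc_geom(1L, cfg$del_mean, j_cap)
  n1 <- rand_nt(rpois(1L, cfg$n1_mean))
  n2 <- rand_nt(rpois(1L, cfg$n2_mean))
  vtrim <- substr(vseq, 1L, lv - del_v)
  dtrim <- if (del_d5 + del_d3 >= ld) "" else
    substr(dseq, del_d5 + 1L, ld - del_d3)
  jtrim <- substr(jseq, del_j + 1L, nchar(jseq))
  seq <- paste0(vtrim, n1, dtrim, n2, jtrim)
  # truth recomputed from the assembly, not from sampling intent
  fo <- db$V$frame_offset[vi]
  trp0 <- nchar(vtrim) + nchar(n1) + nchar(dtrim) + nchar(n2) +
    (db$J$trp_offset[ji] - del_j)
  in_frame <- (trp0 - fo) %% 3L == 0L
  has_stop <- .has_stop_in_frame(seq, fo, trp0 + 3L)
  prod <- if (!in_frame) "unproductive_out_of_frame"
          else if (has_stop) "unproductive_stop" else "in_frame"
  list(seq = seq,
       v_name = db$V$name[vi], d_name = db$D$name[di], j_name = db$J$name[ji],
       del_v = del_v, del_d5 = del_d5, del_d3 = del_d3, del_j = del_j,
       n1 = n1, n2 = n2,
       frame = if (in_frame) "in-frame" else "out-of-frame",
       stop = has_stop, productivity = prod)
}

#' Simulate one IGH V(D)J rearrangement
#'
#' Assembles trimmed-V + N1 + trimmed-D + N2 + trimmed-J with
#' truncated-geometric end deletions and Poisson N-insertion lengths. The
#' productivity class (in-frame without stop vs unproductive) is first drawn
#' from the configured in-frame target fraction, then junctions are
#' rejection-sampled until the recomputed class of the assembled sequence
#' matches, so the marginal in-frame probability equals the target exactly.
#' Conserved Cys/Trp anchor codons always survive trimming.
#'
#' @param db A [make_germline_db()] database.
#' @param cfg A [compartment_config()].
#' @param seed Optional integer seed.
#' @return A list with `seq` (nucleotide string) and `truth` (one-row data
#'   frame: segment names, per-end deletion counts, N1/N2 strings, frame
#'   status, stop flag, productivity class, compartment).
#' @export
simulate_rearrangement <- function(db, cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rec <- simulate_rearrangement_core(db, cfg)
  truth <- data.frame(v_name = rec$v_name, d_name = rec$d_name,
                      j_name = rec$j_name,
                      del_v = rec$del_v, del_d5 = rec$del_d5,
                      del_d3 = rec$del_d3, del_j = rec$del_j,
                      n1 = rec$n1, n2 = rec$n2,
                      frame = rec$frame, stop = rec$stop,
                      productivity = rec$productivity,
                      compartment = cfg$compartment,
                      stringsAsFactors = FALSE)
  list(seq = rec$seq, truth = truth)
}

simulate_rearrangement_core <- function(db, cfg) {
  want_inframe <- runif(1L) < cfg$inframe_target
  for (i in seq_len(cfg$max_attempts)) {
    rec <- draw_rearrangement(db, cfg)
    if ((rec$productivity == "in_frame") == want_inframe) return(rec)
  }
  stop("rejection cap exceeded while sampling a ",
       if (want_inframe) "productive" else "unproductive",
       " rearrangement; configuration is infeasible")
}

#' Simulate the IGH repertoire of a sorted pre-B compartment
#'
#' Draws `n_clones` independent clones under the compartment's junction
#' configuration and optionally emits duplicate reads per clone (to exercise
#' clone collapsing downstream). Ground truth is returned as a separate table
#' and is never embedded in the read headers.
#'
#' @param compartment One of `"preBI_pp"`, `"preBI_nn"`, `"preBII_nn"`,
#'   `"preBII_pp"`.
#' @param n_clones Number of clones (>= 1).
#' @param cfg A [compartment_config()]; defaults to the compartment's default.
#' @param seed Optional integer seed; the same seed reproduces the output
#'   byte-identically.
#' @return A list of class `compartment_repertoire` with `sequences` (named
#'   character vector, one element per read; names are read ids) and `truth`
#'   (data frame, one row per clone with a `clone_id` column).
#' @export
simulate_compartment_repertoire <- function(compartment, n_clones,
                                            cfg = compartment_config(compartment),
                                            seed = NULL) {
  compartment <- match.arg(compartment, BCP_COMPARTMENTS)
  stopifnot(n_clones >= 1)
  if (cfg$compartment != compartment)
    stop("config is for compartment ", cfg$compartment, ", not ", compartment)
  if (!is.null(seed)) set.seed(seed)
  n_clones <- as.integer(n_clones)
  recs <- vector("list", n_clones)
  for (i in seq_len(n_clones)) recs[[i]] <- simulate_rearrangement_core(db = make_germline_db_cached(), cfg = cfg)
  clone_id <- sprintf("%s_cl%06d", compartment, seq_len(n_clones))
  truth <- data.frame(
    clone_id = clone_id,
    v_name = vapply(recs, `[[`, "", "v_name"),
    d_name = vapply(recs, `[[`, "", "d_name"),
    j_name = vapply(recs, `[[`, "", "j_name"),
    del_v = vapply(recs, `[[`, 0L, "del_v"),
    del_d5 = vapply(recs, `[[`, 0L, "del_d5"),
    del_d3 = vapply(recs, `[[`, 0L, "del_d3"),
    del_j = vapply(recs, `[[`, 0L, "del_j"),
    n1 = vapply(recs, `[[`, "", "n1"),
    n2 = vapply(recs, `[[`, "", "n2"),
    frame = vapply(recs, `[[`, "", "frame"),
    stop = vapply(recs, `[[`, NA, "stop"),
    productivity = vapply(recs, `[[`, "", "productivity"),
    compartment = compartment,
    stringsAsFactors = FALSE)
  mult <- rep(1L, n_clones)
  dup <- runif(n_clones) < cfg$dup_prob
  if (any(dup)) mult[dup] <- 1L + sample.int(3L, sum(dup), replace = TRUE)
  seqs <- rep(vapply(recs, `[[`, "", "seq"), mult)
  names(seqs) <- sprintf("%s_r%d", rep(clone_id, mult),
                         sequence(mult))
  structure(list(sequences = seqs, truth = truth, compartment = compartment,
                 config = cfg),
            class = "compartment_repertoire")
}

# the built-in db is deterministic; build it once per session
.db_cache <- new.env(parent = emptyenv())
make_germline_db_cached <- function() {
  if (is.null(.db_cache$db)) .db_cache$db <- make_germline_db()
  .db_cache$db
}

#' Write a simulated compartment repertoire to FASTA plus truth TSV
#'
#' @param rep A [simulate_compartment_repertoire()] result.
#' @param fasta_path Output FASTA path (one record per read).
#' @param truth_path Optional output path for the ground-truth TSV sidecar
#'   (one row per clone). Truth is kept out of the FASTA so it cannot leak
#'   into analysis code.
#' @return Invisibly, `fasta_path`.
#' @export
write_repertoire <- function(rep, fasta_path, truth_path = NULL) {
  dss <- Biostrings::DNAStringSet(rep$sequences)
  Biostrings::writeXStringSet(dss, filepath = fasta_path, width = 80L)
  if (!is.null(truth_path))
    write.table(rep$truth, truth_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(fasta_path)
}
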
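#' Read rearranged IGH sequences from FASTA
#'
#' @param path FASTA file (plain text, one record per read).
#' @return Named character vector of uppercase nucleotide sequences.
#' @export
read_rearrangements <- function(path) {
  dss <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(dss)), names(dss))
}

#' Assign germline V and J segments to rearranged sequences
#'
#' Best-scoring ungapped semi-global alignment of every germline V and J
#' against each query (+1 match, -1 mismatch, no internal gaps; unmutated
#' rearrangements differ from germline only by end trimming, so gaps are not
#' needed). Because junction formation trims the germline ends, the V score
#' is the best prefix of its overlap (the 3'-trimmed remainder is not
#' penalized) and the J score the best suffix (free 5' trimming). Ties are
#' broken by database order. The conserved V-Cys and J-Trp
#' anchor codons are mapped into query coordinates through the alignment;
#' records whose mapped anchors are lost (out of bounds, out of order, or no
#' longer an anchor codon after trimming) are flagged junction-unresolved.
#' Queries where no V or no J reaches its minimum score are flagged
#' unassigned; both flags are tallied by [repertoire_qc()].
#'
#' @param seqs Named character vector of query sequences (ACGTN alphabet,
#'   each >= 60 nt).
#' @param db A [make_germline_db()] database.
#' @param min_score_v,min_score_j Minimum alignment scores. Defaults 40
#'   and 20.
#' @param min_overlap Minimum aligned overlap in nt. Default 10.
#' @return Data frame of class `vdj_records`, one row per query: `query_id`,
#'   `seq`, best `v_name`/`v_score`/`v_shift` and `j_name`/`j_score`/
#'   `j_shift` (shift = 0-based query position of germline position 0),
#'   0-based anchor positions `v_cys_pos` and `j_trp_pos`, `frame_origin`
#'   (0-based query position of the V reading frame), and logical flags
#'   `assigned`, `junction_resolved`.
#' @export
assign_vj <- function(seqs, db, min_score_v = 40, min_score_j = 20,
                      min_overlap = 10L) {
  seqs <- toupper(seqs)
  if (!all(grepl("^[ACGTN]+$", seqs)))
    stop("sequences must use the ACGT(N) alphabet")
  if (any(nchar(seqs) < 60L))
    stop("unassigned: sequence(s) shorter than 60 nt (n = ",
         sum(nchar(seqs) < 60L), ")")
  av <- .align_ungapped(unname(seqs), db$V$seq, as.integer(min_overlap),
                        mode = 1L)  # germline V may be 3'-trimmed
  aj <- .align_ungapped(unname(seqs), db$J$seq, as.integer(min_overlap),
                        mode = 2L)  # germline J may be 5'-trimmed
  bv <- max.col(av$score, ties.method = "first")
  bj <- max.col(aj$score, ties.method = "first")
  n <- length(seqs)
  ix <- cbind(seq_len(n), bv)
  jx <- cbind(seq_len(n), bj)
  v_score <- av$score[ix]; v_shift <- av$shift[ix]
  j_score <- aj$score[jx]; j_shift <- aj$shift[jx]
  assigned <- v_score >= min_score_v & j_score >= min_score_j &
    v_shift < j_shift  # V alignment must precede J in query coordinates
  v_cys <- v_shift + db$V$cys_offset[bv]
  j_trp <- j_shift + db$J$trp_offset[bj]
  frame_origin <- v_shift + db$V$frame_offset[bv]
  # shift a frame origin hanging off the query 5' end to the first complete
  # in-frame position
  neg <- !is.na(frame_origin) & frame_origin < 0L
  frame_origin[neg] <- frame_origin[neg] +
    3L * ceiling(-frame_origin[neg] / 3)
  len <- nchar(seqs)
  v_anchor <- substr(seqs, v_cys + 1L, v_cys + 3L)
  j_anchor <- substr(seqs, j_trp + 1L, j_trp + 3L)
  resolved <- assigned &
    v_cys >= 0L & j_trp + 3L <= len & v_cys + 3L <= j_trp &
    v_anchor %in% c("TGT", "TGC") & j_anchor == "TGG"
  out <- data.frame(query_id = if (is.null(names(seqs))) as.character(seq_len(n))
                    else names(seqs),
                    seq = unname(seqs),
                    v_name = db$V$name[bv], v_score = v_score,
                    v_shift = v_shift,
                    j_name = db$J$name[bj], j_score = j_score,
                    j_shift = j_shift,
                    v_cys_pos = v_cys, j_trp_pos = j_trp,
                    frame_origin = frame_origin,
                    assigned = assigned, junction_resolved = resolved,
                    stringsAsFactors = FALSE)
  class(out) <- c("vdj_records", "data.frame")
  out
}

#' Extract the CDR3 junction
#'
#' The CDR3 nucleotide string is the query substring strictly between the
#' conserved V-Cys codon and the J-Trp codon (both anchors excluded).
#' Records whose anchors are unresolved get `NA` and keep their
#' junction-unresolved flag.
#'
#' @param records A `vdj_records` data frame from [assign_vj()].
#' @return `records` with a `cdr3_nt` column added.
#' @export
extract_junction <- function(records) {
  cdr3 <- rep(NA_character_, nrow(records))
  ok <- records$junction_resolved
  cdr3[ok] <- substr(records$seq[ok], records$v_cys_pos[ok] + 4L,
                     records$j_trp_pos[ok])
  records$cdr3_nt <- cdr3
  records
}

#' Classify rearrangement productivity
#'
#' A rearrangement is in-frame when the distance from the V reading-frame
#' origin to the J-Trp codon start is a multiple of 3; it carries a stop when
#' translation from the V frame origin through the end of the J anchor codon
#' contains a stop codon. Productivity is `in_frame` only for in-frame,
#' stop-free rearrangements; otherwise `unproductive_out_of_frame` or
#' `unproductive_stop`. The CDR3 amino-acid string is added for in-frame
#' records. Junction-unresolved records get class `NA` (QC tally).
#'
#' @param records A `vdj_records` data frame with `cdr3_nt`
#'   ([extract_junction()]).
#' @return `records` with `frame`, `stop`, `productivity` and `cdr3_aa`
#'   columns added.
#' @export
classify_productivity <- function(records) {
  n <- nrow(records)
  frame <- rep(NA_character_, n)
  stp <- rep(NA, n)
  prod <- rep(NA_character_, n)
  aa <- rep(NA_character_, n)
  ok <- records$junction_resolved
  if (any(ok)) {
    inf <- (records$j_trp_pos[ok] - records$frame_origin[ok]) %% 3L == 0L
    frame[ok] <- ifelse(inf, "in-frame", "out-of-frame")
    stp[ok] <- .has_stop_in_frame(records$seq[ok],
                                  records$frame_origin[ok],
                                  records$j_trp_pos[ok] + 3L)
    prod[ok] <- ifelse(!inf, "unproductive_out_of_frame",
                       ifelse(stp[ok], "unproductive_stop", "in_frame"))
    tr <- ok & frame == "in-frame" & !is.na(records$cdr3_nt)
    aa[tr] <- translate_nt(records$cdr3_nt[tr])
  }
  records$frame <- frame
  records$stop <- stp
  records$productivity <- prod
  records$cdr3_aa <- aa
  records
}

translate_nt <- function(nt) {
  out <- character(length(nt))
  nz <- nchar(nt) > 0L
  if (any(nz))
    out[nz] <- as.character(Biostrings::translate(
      Biostrings::DNAStringSet(nt[nz]), no.init.codon = TRUE))
  out
}

#' Collapse reads into clones
#'
#' A clone is a unique combination of V gene, J gene and CDR3 nucleotide
#' sequence; one representative (the first-seen record) is kept per clone and
#' the read multiplicity is recorded. Collapsing an already-collapsed clone
#' set sums multiplicities, so the operation is idempotent on clone
#' identities. Unassigned or junction-unresolved records are excluded (see
#' [repertoire_qc()]).
#'
#' @param records A classified `vdj_records` data frame, or a `clone_set`.
#' @return Data frame of class `clone_set`: `v_name`, `j_name`, `cdr3_nt`,
#'   `cdr3_aa`, `productivity`, `multiplicity`, `representative` (query id).
#' @export
collapse_clones <- function(records) {
  if (inherits(records, "clone_set")) {
    weights <- records$multiplicity
    ids <- records$representative
  } else {
    records <- records[records$junction_resolved &
                         !is.na(records$productivity), , drop = FALSE]
    weights <- rep(1L, nrow(records))
    ids <- records$query_id
  }
  if (nrow(records) == 0L) stop("no resolved records to collapse")
  key <- paste(records$v_name, records$j_name, records$cdr3_nt, sep = "\r")
  first <- !duplicated(key)
  rs <- rowsum(weights, key)
  mult <- setNames(as.vector(rs), rownames(rs))
  out <- data.frame(v_name = records$v_name[first],
                    j_name = records$j_name[first],
                    cdr3_nt = records$cdr3_nt[first],
                    cdr3_aa = records$cdr3_aa[first],
                    productivity = records$productivity[first],
                    multiplicity = as.integer(mult[key[first]]),
                    representative = ids[first],
                    stringsAsFactors = FALSE)
  class(out) <- c("clone_set", "data.frame")
  out
}

#' Count positively charged residues in a CDR3 amino-acid string
#'
#' Positive charge is counted as occurrences of arginine (R), lysine (K) and
#' histidine (H).
#'
#' @param aa Character vector of amino-acid strings.
#' @return Integer vector of positive-residue counts.
#' @export
cdr3_positive_charges <- function(aa) {
  nchar(gsub("[^RKH]", "", aa))
}

CHARGE_CLASSES <- c("0", "1", "2", ">=3")

#' Clone-level repertoire statistics per compartment
#'
#' Computes, over collapsed clones (never reads): clone counts, the in-frame
#' clone fraction, the in-frame : unproductive ratio, the CDR3 amino-acid
#' length distribution of in-frame clones, and the proportions of in-frame
#' CDR3s with 0, 1, 2 or >= 3 positively charged residues (R/K/H).
#'
#' @param clone_sets A single `clone_set` or a named list of them (one per
#'   sorted compartment).
#' @return A list of class `repertoire_stats`: `summary` (data frame with one
#'   row per compartment: `compartment`, `n_clones`, `n_inframe`,
#'   `n_unproductive`, `inframe_fraction`, `inframe_unproductive_ratio`,
#'   `mean_cdr3_aa_length`), `cdr3_aa_lengths` (list of integer vectors) and
#'   `charge_proportions` (matrix, compartments x charge classes, rows
#'   summing to 1).
#' @export
repertoire_stats <- function(clone_sets) {
  if (inherits(clone_sets, "clone_set")) clone_sets <- list(clone_sets)
  if (is.null(names(clone_sets)))
    names(clone_sets) <- paste0("compartment", seq_along(clone_sets))
  rows <- list(); lens <- list()
  charge <- matrix(NA_real_, length(clone_sets), length(CHARGE_CLASSES),
                   dimnames = list(names(clone_sets), CHARGE_CLASSES))
  for (i in seq_along(clone_sets)) {
    cs <- clone_sets[[i]]
    if (!nrow(cs)) stop("empty clone set: ", names(clone_sets)[i])
    n <- nrow(cs)
    n_if <- sum(cs$productivity == "in_frame")
    n_un <- n - n_if
    aa <- cs$cdr3_aa[cs$productivity == "in_frame"]
    l <- nchar(aa)
    lens[[names(clone_sets)[i]]] <- l
    ch <- cdr3_positive_charges(aa)
    cls <- cut(ch, breaks = c(-0.5, 0.5, 1.5, 2.5, Inf),
               labels = CHARGE_CLASSES)
    charge[i, ] <- if (length(ch)) as.vector(table(cls)) / length(ch)
                   else NA_real_
    rows[[i]] <- data.frame(compartment = names(clone_sets)[i],
                            n_clones = n, n_inframe = n_if,
                            n_unproductive = n_un,
                            inframe_fraction = n_if / n,
                            inframe_unproductive_ratio =
                              if (n_un > 0) n_if / n_un else Inf,
                            mean_cdr3_aa_length =
                              if (length(l)) mean(l) else NA_real_,
                            stringsAsFactors = FALSE)
  }
  structure(list(summary = do.call(rbind, rows),
                 cdr3_aa_lengths = lens,
                 charge_proportions = charge,
                 schema_version = BCPFLOW_SCHEMA),
            class = "repertoire_stats")
}

#' QC tallies for a set of processed rearrangement records
#'
#' @param records A `vdj_records` data frame after [assign_vj()].
#' @return List with `n_reads`, `n_unassigned` and `n_junction_unresolved`.
#' @export
repertoire_qc <- function(records) {
  list(n_reads = nrow(records),
       n_unassigned = sum(!records$assigned),
       n_junction_unresolved = sum(records$assigned &
                                     !records$junction_resolved))
}

#' Run the full repertoire pipeline on one compartment's reads
#'
#' assign -> extract junction -> classify productivity -> collapse clones.
#'
#' @param seqs Named character vector of reads, or a FASTA path, or a
#'   `compartment_repertoire`.
#' @param db Germline database. Default the built-in mini-database.
#' @param ... Passed to [assign_vj()].
#' @return List with `records` (classified `vdj_records`), `clones`
#'   (`clone_set`) and `qc`.
#' @export
analyze_repertoire <- function(seqs, db = make_germline_db(), ...) {
  if (inherits(seqs, "compartment_repertoire")) seqs <- seqs$sequences
  if (length(seqs) == 1L && file.exists(seqs)) seqs <- read_rearrangements(seqs)
  records <- assign_vj(seqs, db, ...)
  records <- extract_junction(records)
  records <- classify_productivity(records)
  list(records = records, clones = collapse_clones(records),
       qc = repertoire_qc(records))
}
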
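db <- make_germline_db()

test_that("perfect germline concatenations recover both segments with full scores", {
  for (vi in c(1L, 4L)) for (ji in c(2L, 5L)) {
    q <- paste0(db$V$seq[vi], db$J$seq[ji])
    rec <- assign_vj(setNames(q, "q1"), db)
    expect_identical(rec$v_name, db$V$name[vi])
    expect_identical(rec$j_name, db$J$name[ji])
    expect_identical(rec$v_score, nchar(db$V$seq[vi]))
    expect_identical(rec$j_score, nchar(db$J$seq[ji]))
    expect_true(rec$junction_resolved)
  }
  expect_error(assign_vj("ACGTACGTACGTACGTACGTACGTACGTAC", db),
               "unassigned")
  expect_error(assign_vj("ACGUACGU", db), "alphabet")
})

test_that("the junction is the substring strictly between the anchors", {
  v <- db$V$seq[1]; j <- db$J$seq[1]
  ins <- "AACCGGTTA"
  q <- paste0(v, ins, j)
  rec <- extract_junction(assign_vj(setNames(q, "q"), db))
  # CDR3 = V tail after the Cys codon + insert + J region before the Trp codon
  expected <- paste0(substr(v, db$V$cys_offset[1] + 4L, nchar(v)), ins,
                     substr(j, 1L, db$J$trp_offset[1]))
  expect_identical(rec$cdr3_nt, expected)

  # anchors adjacent: empty CDR3
  q2 <- paste0(substr(v, 1L, db$V$cys_offset[1] + 3L),
               substr(j, db$J$trp_offset[1] + 1L, nchar(j)))
  rec2 <- extract_junction(assign_vj(setNames(q2, "q2"), db))
  expect_true(rec2$junction_resolved)
  expect_identical(rec2$cdr3_nt, "")

  # V Cys anchor trimmed away: junction-unresolved
  q3 <- paste0(substr(v, 1L, 62L), strrep("CA", 15L), j)
  rec3 <- extract_junction(assign_vj(setNames(q3, "q3"), db))
  expect_false(rec3$junction_resolved)
  expect_true(is.na(rec3$cdr3_nt))
  r3c <- classify_productivity(rec3)
  expect_true(is.na(r3c$productivity))
})

test_that("productivity classification matches frame and stop-codon rules", {
  v <- db$V$seq[1]; j <- db$J$seq[1]  # frame offset 0, Trp offset 15
  # 90 + 6 + 15 is divisible by 3 and GGCGGC is stop-free: in-frame
  rec <- classify_productivity(extract_junction(
    assign_vj(setNames(paste0(v, "GGCGGC", j), "a"), db)))
  expect_identical(rec$productivity, "in_frame")
  expect_identical(nchar(rec$cdr3_aa) * 3L, nchar(rec$cdr3_nt))
  # one extra junction nucleotide shifts the J anchor out of frame
  rec2 <- classify_productivity(extract_junction(
    assign_vj(setNames(paste0(v, "GGGCGGC", j), "b"), db)))
  expect_identical(rec2$productivity, "unproductive_out_of_frame")
  # an in-frame TAA in the junction makes an unproductive-stop rearrangement
  rec3 <- classify_productivity(extract_junction(
    assign_vj(setNames(paste0(v, "TAAGGC", j), "c"), db)))
  expect_identical(rec3$frame, "in-frame")
  expect_identical(rec3$productivity, "unproductive_stop")
})

test_that("the pipeline recovers generator truth on simulated records", {
  rep <- simulate_compartment_repertoire("preBII_pp", 1000, seed = 621)
  res <- analyze_repertoire(rep, db)
  expect_identical(res$qc$n_unassigned, 0L)
  expect_identical(res$qc$n_junction_unresolved, 0L)
  m <- match(sub("_r\\d+$", "", res$records$query_id), rep$truth$clone_id)
  expect_gte(mean(res$records$v_name == rep$truth$v_name[m]), 0.99)
  expect_gte(mean(res$records$j_name == rep$truth$j_name[m]), 0.99)
  # frame/stop/productivity agree with the generator truth on every record
  expect_identical(res$records$productivity, rep$truth$productivity[m])
  expect_identical(res$records$frame, rep$truth$frame[m])
  expect_identical(res$records$stop, rep$truth$stop[m])
})

test_that("clone collapsing follows the V/J/CDR3 rule and is idempotent", {
  v <- db$V$seq[2]; j <- db$J$seq[3]
  q <- c(r1 = paste0(v, "AAGGCC", j),
         r2 = paste0(v, "AAGGCC", j),   # identical read
         r3 = paste0(v, "AAGGCG", j))   # same V and J, CDR3 differs by 1 nt
  recs <- classify_productivity(extract_junction(assign_vj(q, db)))
  clones <- collapse_clones(recs)
  expect_identical(nrow(clones), 2L)
  expect_identical(clones$multiplicity[clones$representative == "r1"], 2L)
  expect_identical(clones$multiplicity[clones$representative == "r3"], 1L)
  again <- collapse_clones(clones)
  expect_identical(again$cdr3_nt, clones$cdr3_nt)
  expect_identical(again$multiplicity, clones$multiplicity)
})

test_that("read duplication never changes clone-level statistics", {
  rep <- simulate_compartment_repertoire(
    "preBI_nn", 400, compartment_config("preBI_nn", dup_prob = 0), seed = 622)
  base <- analyze_repertoire(rep$sequences, db)
  dup_seqs <- rep(rep$sequences, each = 3L)
  names(dup_seqs) <- sprintf("%s_dup%d", rep(names(rep$sequences), each = 3L),
                             1:3)
  dup <- analyze_repertoire(dup_seqs, db)
  s1 <- repertoire_stats(list(x = base$clones))$summary
  s2 <- repertoire_stats(list(x = dup$clones))$summary
  expect_identical(s1$n_clones, s2$n_clones)
  expect_identical(s1$inframe_fraction, s2$inframe_fraction)
  expect_identical(s1$mean_cdr3_aa_length, s2$mean_cdr3_aa_length)
  expect_identical(sort(base$clones$cdr3_nt), sort(dup$clones$cdr3_nt))
})

test_that("repertoire statistics compute fractions, ratios and charge classes", {
  clones <- structure(data.frame(
    v_name = "IGHV1-S1", j_name = "IGHJ1-S1",
    cdr3_nt = sprintf("seqvar%03d", 1:100),
    cdr3_aa = c(rep("ARDKHW", 40), rep("GSSYFD", 40), rep(NA, 20)),
    productivity = rep(c("in_frame", "unproductive_out_of_frame"),
                       c(80, 20)),
    multiplicity = 1L, representative = sprintf("r%d", 1:100),
    stringsAsFactors = FALSE), class = c("clone_set", "data.frame"))
  st <- repertoire_stats(list(preBII_nn = clones))
  expect_equal(st$summary$inframe_fraction, 0.80)
  expect_equal(st$summary$inframe_unproductive_ratio, 4)
  # "ARDKHW" has R, K and H -> class ">=3"; "GSSYFD" has none -> class "0"
  expect_identical(cdr3_positive_charges(c("ARDKHW", "GSSYFD")), c(3L, 0L))
  expect_equal(unname(st$charge_proportions[1, ]), c(0.5, 0, 0, 0.5))
  expect_equal(sum(st$charge_proportions[1, ]), 1)
  expect_error(repertoire_stats(list(x = clones[0, ])), "empty clone set")
})

test_that("charge-class proportions are compartment-independent for identical junction configs", {
  # preBII_nn and preBII_pp share the default deletion/N composition and
  # differ only in their in-frame target
  st <- lapply(c("preBII_nn", "preBII_pp"), function(comp) {
    rep <- simulate_compartment_repertoire(comp, 20000, seed = 623)
    repertoire_stats(analyze_repertoire(rep, db)$clones)$charge_proportions
  })
  expect_lt(max(abs(st[[1]] - st[[2]])), 0.02)
})
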
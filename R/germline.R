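#' Built-in synthetic IGH germline mini-database
#'
#' Returns a small, fully synthetic germline segment database used by the
#' rearrangement simulator and the V/J assigner. Sequences are invented but
#' structured like IGH segments: every V segment carries a conserved cysteine
#' codon (TGT/TGC) near its 3' end followed by a short trimmable tail, is
#' stop-free when translated from its reading-frame offset through the Cys
#' anchor, and every J segment carries the conserved tryptophan codon (TGG)
#' at a recorded offset. Segment names carry an `-S` suffix to mark them as
#' synthetic stand-ins, not real IMGT alleles.
#'
#' @return An object of class `germline_db`: a list with data frames `V`
#'   (`name`, `seq`, `frame_offset`, `cys_offset`), `D` (`name`, `seq`) and
#'   `J` (`name`, `seq`, `trp_offset`). All offsets are 0-based.
#' @examples
#' db <- make_germline_db()
#' nrow(db$V)
#' @export
make_germline_db <- function() {
  V <- data.frame(
    name = c("IGHV1-S1", "IGHV2-S1", "IGHV3-S1", "IGHV4-S1", "IGHV5-S1", "IGHV6-S1"),
    seq = c(
      "ACCATGAGAGCCTTAGAGGCTTCATATCAAGTTCTGGGACGTCAAGTCCCGTCTTCTGTGCTCCATGGTTCTACTAGGTGGTGTGCGAGA",
      "GGCGTCTCGAGCGTTCTCCCGCAGGGCAGTGGATGCCTCCGTCAGCCTGGTCGTTTAGGGCGAAAGACTGACAATCCCCAATGCGCGAGA",
      "GAGGACACGTTCCGCGGGTCCATTCGTTACCACCACCCCATTGTTCCGAGACATTGTCATCCATTACCTTCGCAAATTACTTGTGCGAGA",
      "CCAGAAACTGGGAGCATGTTACGAATTTAGGATCCTGGTTTCCTGACTCTATCATTCCCCGAGACCAAGGCCGGCCAGGATATTGTGCGAGA",
      "CAGGATCTACTGGTTTCTATACGTGGAAGCCTCCACAGCGTAAAGATATCGCACAACAGTGTAAGCCGGCCATCTGACTGCTGCGCGAGA",
      "TCCGACCTTAACGACATCAATGGTGGCCGCATCGAGGCCGACGAACTACTTCGGGGTTACTTGTTTGAAAGAGACCGGACTTGTGCGAGA"),
    frame_offset = c(0L, 0L, 0L, 2L, 0L, 0L),
    cys_offset = c(81L, 81L, 81L, 83L, 81L, 81L),
    stringsAsFactors = FALSE)
  D <- data.frame(
    name = c("IGHD1-S1", "IGHD2-S1", "IGHD3-S1", "IGHD4-S1"),
    seq = c(
      "GAAATTGAGAACTGAAC",
      "TTGGGAATACTGTCTCAGTGA",
      "TATCGATAAATCTCCA",
      "AGCGGTATGCGGGATAGTTGGGGT"),
    stringsAsFactors = FALSE)
  J <- data.frame(
    name = c("IGHJ1-S1", "IGHJ2-S1", "IGHJ3-S1", "IGHJ4-S1", "IGHJ5-S1"),
    seq = c(
      "TATGGGATACAATCTTGGCCAATTGTTCCGCCTCCATGCGGT",
      "GGTAGGGACCAGCCTCATTGGGGAGTCCCGATAGCCCCTCTTGAC",
      "ATCAACCCGATCGGTATCAGGTGGCTGCGCTCGGAATACGGTTCTGGC",
      "CCGAAGCGCGTGCTTTTTCTTGGGAAATACCCTGCAAAGTCATGCCC",
      "CAGAGATAAGTGAAAATGGGGAGGGTCTCAGCCTACTTTTAGT"),
    trp_offset = c(15L, 18L, 21L, 20L, 16L),
    stringsAsFactors = FALSE)
  db <- structure(list(V = V, D = D, J = J), class = "germline_db")
  validate_germline_db(db)
  db
}

#' Validate a germline segment database
#'
#' Checks the structural invariants the simulator and assigner rely on:
#' at least 5 V, 3 D and 4 J segments; uppercase ACGT alphabet; every V
#' Cys-anchor codon is TGT or TGC and the V reading frame is stop-free through
#' the anchor; every J Trp-anchor codon is TGG.
#'
#' @param db A `germline_db` object.
#' @return `db`, invisibly. Errors if any invariant is violated.
#' @export
validate_germline_db <- function(db) {
  stopifnot(is.list(db), all(c("V", "D", "J") %in% names(db)))
  if (nrow(db$V) < 5L || nrow(db$D) < 3L || nrow(db$J) < 4L)
    stop("germline db too small: need >=5 V, >=3 D, >=4 J segments")
  all_seqs <- c(db$V$seq, db$D$seq, db$J$seq)
  if (!all(grepl("^[ACGT]+$", all_seqs)))
    stop("germline sequences must be uppercase ACGT only")
  for (i in seq_len(nrow(db$V))) {
    s <- db$V$seq[i]; fo <- db$V$frame_offset[i]; cy <- db$V$cys_offset[i]
    if ((cy - fo) %% 3L != 0L)
      stop("V Cys anchor not in the declared reading frame: ", db$V$name[i])
    anchor <- substr(s, cy + 1L, cy + 3L)
    if (!anchor %in% c("TGT", "TGC"))
      stop("V Cys anchor codon must be TGT or TGC: ", db$V$name[i])
    starts <- seq(fo + 1L, cy + 1L, by = 3L)
    cds <- substring(s, starts, starts + 2L)
    if (any(cds %in% c("TAA", "TAG", "TGA")))
      stop("V reading frame contains a stop codon before the Cys anchor: ",
           db$V$name[i])
  }
  for (i in seq_len(nrow(db$J))) {
    if (substr(db$J$seq[i], db$J$trp_offset[i] + 1L, db$J$trp_offset[i] + 3L) != "TGG")
      stop("J Trp anchor codon must be TGG: ", db$J$name[i])
  }
  invisible(db)
}
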
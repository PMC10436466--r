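# Toy germline CDR3 flanks.
#
# Eight V-segment 3' flanks (the germline-encoded CDR3 prefix, starting at
# the conserved cysteine codon, frame 0) and six J-segment 5' flanks (the
# suffix ending at the conserved phenylalanine). Lengths are chosen so that
# every residue class mod 3 is represented on both sides: for any N(D)N
# length there is a (V, J) pair keeping the CDR3 in frame. These are
# fixtures for simulation, not biological references; gene labels are toy.

TOY_V_SEGMENTS <- data.frame(
  v_call = paste0("TRBVS", 1:8),
  nt = c(
    "TGTGCCAGCAGT",    # CASS, 12 nt
    "TGTGCCAGCAGTTTA", # CASSL, 15 nt
    "TGCGCCAGCAGC",    # CASS, 12 nt
    "TGTGCCACCAGCA",   # CAT S + 1 nt, 13 nt
    "TGTGCCAGCAGTGA",  # CASS + 2 nt, 14 nt
    "TGTGCCTGGA",      # CAW + 1 nt, 10 nt
    "TGTGCCAGCAG",     # CAS + 2 nt, 11 nt
    "TGTGCTAGCAGTTTG"  # CASSL, 15 nt
  ),
  stringsAsFactors = FALSE
)

TOY_J_SEGMENTS <- data.frame(
  j_call = paste0("TRBJS", 1:6),
  nt = c(
    "AATGAGCAGTTCTTT",  # 15 nt (mod 0)
    "GAGCAGTACTTC",     # 12 nt (mod 0)
    "TGAGCAGTTCTTT",    # 13 nt (mod 1)
    "CTACGAGCAGTACTTC", # 16 nt (mod 1)
    "ACGAGCAGTACTTC",   # 14 nt (mod 2)
    "CCCAGCATTTT"       # 11 nt (mod 2)
  ),
  stringsAsFactors = FALSE
)

#' Toy germline segment set used by the repertoire generator
#'
#' @return A list with data frames `v` (`v_call`, `nt`) and `j`
#'   (`j_call`, `nt`): short CDR3 flank sequences bracketing the simulated
#'   N(D)N junction.
#' @export
toy_germline <- function() {
  list(v = TOY_V_SEGMENTS, j = TOY_J_SEGMENTS)
}
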
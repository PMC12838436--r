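# Cohort findings fixture: the 17 variants with added interpretive value
# across 13 individuals, transcribed into the FindingsRecord layout used
# by the reporting module. Rows published without an individual
# identifier receive distinct synthetic ids (SYN_*); those findings were
# not reported (reported = FALSE), which is only permitted for likely
# benign / benign records.

#' Findings table fixture
#'
#' Returns one row per variant: `individual_id`, `variant_id`,
#' `variant_type` (SNV/INDEL, SV, STR, OTHER), `gene`, `classification`
#' (P, LP, VUS_hot, VUS, LB, B), `added_value_note`, `reported`.
#'
#' @return A data.frame with 17 rows covering 13 individuals.
#' @examples
#' f <- table2Fixture()
#' nrow(f)                         # 17
#' length(unique(f$individual_id)) # 13
#' @export
table2Fixture <- function() {
  rec <- function(ind, var, type, gene, cls, note, rep = TRUE)
    data.frame(individual_id = ind, variant_id = var, variant_type = type,
               gene = gene, classification = cls, added_value_note = note,
               reported = rep, stringsAsFactors = FALSE)
  out <- rbind(
    rec("RD_P694", "SGCA_c.557A>T", "SNV/INDEL", "SGCA", "LP",
        "phased in trans with c.348_352dup, 585 bp apart"),
    rec("RD_P694", "SGCA_c.348_352dup", "SNV/INDEL", "SGCA", "LP",
        "phased in trans with c.557A>T, 585 bp apart"),
    rec("RD_P712", "COL12A1_c.8861G>A", "SNV/INDEL", "COL12A1", "VUS_hot",
        "phased in trans with c.165C>G, 105 kb apart"),
    rec("RD_P712", "COL12A1_c.165C>G", "SNV/INDEL", "COL12A1", "VUS_hot",
        "phased in trans with c.8861G>A, 105 kb apart"),
    rec("RD_P623", "SMN1_homdel", "SV", "SMN1", "P",
        "paralog phasing: no SMN1 copy, four SMN2 copies"),
    rec("RD_P695", "FGF14_inv13", "SV", "FGF14", "P",
        "breakpoint mapping; 7.6 kb deletion at one breakpoint"),
    rec("RD_P695", "inv10_pericentric", "SV", "multiple", "LB",
        "pericentric inversion of chromosome 10 detected"),
    rec("RD_P633", "der14_t8_14", "SV", "multiple", "P",
        "telomeric sequence at one breakpoint; acrocentric p-arm link"),
    rec("RD_P651", "cgr_9p_del_inv_dup", "SV", "multiple", "P",
        "resolved CGR structure (DEL-INV-DUP)"),
    rec("RD_P655", "ring18_mosaic", "SV", "multiple", "P",
        "resolved CGR structure (mosaic ring chromosome 18)"),
    rec("SYN_A", "cgr_9p_complex", "SV", "none", "LB",
        "SV called, breakpoints mapped; no disease gene disrupted", FALSE),
    rec("SYN_A", "cgr_10p_complex", "SV", "none", "LB",
        "SV called, breakpoints mapped; no disease gene disrupted", FALSE),
    rec("SYN_B", "cgr_1p_complex", "SV", "none", "LB",
        "SV called, breakpoints mapped; no disease gene disrupted", FALSE),
    rec("RD_P698", "FMR1_full_654", "STR", "FMR1", "P",
        "654-unit CGG expansion; interruption loss; hypermethylated"),
    rec("SYN_C", "FMR1_premut_60", "STR", "FMR1", "LB",
        "60-unit expansion with interrupting motifs, unmethylated", FALSE),
    rec("SYN_D", "ATXN1_37", "STR", "ATXN1", "LB",
        "31/37 alleles, two interrupting CAT motifs each", FALSE),
    rec("RD_P706", "UPD15_maternal_isodisomy", "OTHER", "multiple", "P",
        "methylation analysis confirms Prader-Willi diagnosis"))
  out
}
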
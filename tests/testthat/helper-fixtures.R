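# Shared fixtures: a tiny SAM writer and a cached small synthetic study so
# several test files can reuse one pipeline run.

write_test_sam <- function(path, refs, reads) {
  # refs: named integer vector of reference lengths
  # reads: data.frame with qname, flag, rname, pos, mapq, cigar, seq
  hd <- c("@HD\tVN:1.6\tSO:unknown",
          sprintf("@SQ\tSN:%s\tLN:%d", names(refs), refs))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
                  reads$qname, reads$flag, reads$rname, reads$pos,
                  reads$mapq, reads$cigar, reads$seq)
  writeLines(c(hd, body), path)
  path
}

# one numbered 76-nt test family with a fixed sequence
test_family <- function(id = "Fam_A",
                        seq = paste(rep(c("A", "C", "G", "U"), 19),
                                    collapse = "")) {
  assign_sprinzl(family_reference(id, seq, members = paste0(id, "-1")))
}

.study_cache <- new.env(parent = emptyenv())

small_study <- function() {
  if (is.null(.study_cache$st)) {
    cfg <- sim_config(seed = 101, n_families = 4, depth = 2000)
    .study_cache$cfg <- cfg
    .study_cache$st <- simulate_study(cfg)
  }
  .study_cache$st
}

small_result <- function() {
  if (is.null(.study_cache$res)) {
    st <- small_study()
    .study_cache$res <- run_study(st, rules = rules_from_truth(st$truth))
  }
  .study_cache$res
}
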
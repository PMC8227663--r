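# Shared fixtures and independent oracles for the test suite.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_seq <- function(x, rate) {
  ch <- strsplit(x, "", fixed = TRUE)[[1]]
  i <- which(stats::runif(length(ch)) < rate)
  ch[i] <- vapply(ch[i], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
  paste(ch, collapse = "")
}

rc_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# single shared small simulated collection (cached across test files)
.fixture_env <- new.env(parent = emptyenv())

small_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    .fixture_env$sim <- simulate_collection(
      sim_config(n_genomes = 5, core_families = 20, shell_families = 10,
                 cloud_families = 0, unique_per_genome = 2,
                 core_snp_rate = 0.002, seed = 42))
  }
  .fixture_env$sim
}

small_matrix <- function() {
  if (is.null(.fixture_env$mat)) {
    sim <- small_sim()
    ids <- vapply(sim$genomes, `[[`, character(1), "genome_id")
    .fixture_env$mat <- build_matrix(cluster_genes(sim$genomes), ids)
  }
  .fixture_env$mat
}

# a single-contig genome wrapping one sequence, for screening subjects
wrap_genome <- function(id, seq) {
  annotated_genome(id, setNames(seq, paste0(id, "_ctg1")))
}

# hit verdict of the in-house screen for a raw query/subject pair
engine_hit <- function(query, subject, params = screen_params()) {
  cand <- marker_candidate("QUERY", "q1", query)
  out <- screen_inhouse(cand, list(wrap_genome("SUBJ", subject)), params)
  out$status$nt_unique_inhouse == "fail"
}

# Independent Smith-Waterman oracle applying the same hit definition via
# Biostrings: best local alignment on either strand (BLASTN-like scores),
# plus a longest-common-substring check for the exact-match rule.
.sw_mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                    baseOnly = TRUE)
.lcs_mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1,
                                                     mismatch = -1e6,
                                                     baseOnly = TRUE)

sw_oracle_hit <- function(q, s, min_len = 60, min_id = 0.8, exact_min = 25) {
  hit_id <- function(a, b) {
    al <- Biostrings::pairwiseAlignment(a, b, type = "local",
                                        substitutionMatrix = .sw_mat,
                                        gapOpening = 5, gapExtension = 2)
    cols <- nchar(as.character(Biostrings::pattern(al)))
    cols >= min_len && (Biostrings::nmatch(al) / cols) >= min_id
  }
  lcs <- function(a, b) {
    Biostrings::score(Biostrings::pairwiseAlignment(
      a, b, type = "local", substitutionMatrix = .lcs_mat,
      gapOpening = 1e6, gapExtension = 1e6))
  }
  rc <- rc_chr(s)
  hit_id(q, s) || hit_id(q, rc) || lcs(q, s) >= exact_min ||
    lcs(q, rc) >= exact_min
}

# write a tiny FASTA + GFF3 pair for read_genome tests
write_toy_genome_files <- function(contigs, features, dir = tempfile()) {
  dir.create(dir)
  fa <- file.path(dir, "toy.fna")
  writeLines(unlist(lapply(names(contigs), function(id)
    c(paste0(">", id), contigs[[id]]))), fa)
  gff <- file.path(dir, "toy.gff")
  writeLines(c("##gff-version 3", features), gff)
  list(fasta = fa, gff = gff)
}
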
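# Synthetic genome collections with known pangenome structure: every
# pipeline stage can be validated against a planted truth without any
# external data.  Gene families are fabricated as random open reading
# frames; core families receive per-genome point substitutions; shell and
# cloud families are carried by genome subsets drawn within their frequency
# bands; strain-unique genes are rejection-sampled to share no 15-mer with
# any other emitted sequence, giving the nucleotide screening stage a clean
# positive control.

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Simulation configuration
#'
#' Defaults describe the reference study condition used throughout the
#' package's validation: a 20-genome collection with 300 core, 500 shell and
#' 800 cloud families, 5 planted unique genes per genome, and a core
#' substitution rate of 0.003 per site per genome.  Shell carriage sits in
#' the [0.15, 0.95) band and cloud carriage below 0.15 with at least two
#' carriers (a single-carrier accessory family would be indistinguishable
#' from a planted unique gene).
#'
#' @param n_genomes number of genomes
#' @param core_families,shell_families,cloud_families family counts per
#'   compartment
#' @param unique_per_genome planted strain-unique genes per genome
#' @param gene_len_mean,gene_len_sd log-normal gene length moments (bp);
#'   lengths are clamped to [150, 6000] and rounded to whole codons
#' @param core_snp_rate substitutions per site per genome in core genes
#' @param shell_carriage_prob,cloud_carriage_prob per-genome carriage
#'   probabilities within the shell/cloud bands
#' @param seed RNG seed; a fixed seed yields byte-identical output
#' @return object of class `sim_config`
#' @export
sim_config <- function(n_genomes = 20L, core_families = 300L,
                       shell_families = 500L, cloud_families = 800L,
                       unique_per_genome = 5L, gene_len_mean = 900,
                       gene_len_sd = 500, core_snp_rate = 0.003,
                       shell_carriage_prob = 0.5,
                       cloud_carriage_prob = 0.05, seed = 1L) {
  cfg <- list(n_genomes = as.integer(n_genomes),
              core_families = as.integer(core_families),
              shell_families = as.integer(shell_families),
              cloud_families = as.integer(cloud_families),
              unique_per_genome = as.integer(unique_per_genome),
              gene_len_mean = gene_len_mean, gene_len_sd = gene_len_sd,
              core_snp_rate = core_snp_rate,
              shell_carriage_prob = shell_carriage_prob,
              cloud_carriage_prob = cloud_carriage_prob,
              seed = as.integer(seed))
  stopifnot(cfg$n_genomes >= 1L, cfg$core_families >= 0L,
            cfg$shell_families >= 0L, cfg$cloud_families >= 0L,
            cfg$unique_per_genome >= 0L, cfg$core_snp_rate >= 0,
            cfg$gene_len_mean >= 150, cfg$gene_len_sd > 0)
  if (shell_carriage_prob < 0.15 || shell_carriage_prob >= 0.95)
    stop("shell_carriage_prob must lie in [0.15, 0.95)", call. = FALSE)
  if (cloud_carriage_prob < 0.005 || cloud_carriage_prob >= 0.15)
    stop("cloud_carriage_prob must lie in [0.005, 0.15)", call. = FALSE)
  n <- cfg$n_genomes
  if (cfg$shell_families > 0L && length(shell_band(n)) == 0L)
    stop("no legal shell carriage count for ", n,
         " genomes; increase n_genomes or set shell_families = 0",
         call. = FALSE)
  if (cfg$cloud_families > 0L && length(cloud_band(n)) == 0L)
    stop("no legal cloud carriage count for ", n,
         " genomes (cloud families need >= 2 carriers below 15%);",
         " increase n_genomes or set cloud_families = 0", call. = FALSE)
  structure(cfg, class = "sim_config")
}

# Legal carriage counts per band.  Accessory families are kept off the
# unique (k = 1) and core-ish (k/N >= 0.95) edges so the realized
# compartments match the planted ones exactly.
shell_band <- function(n) {
  lo <- max(2L, ceiling(0.15 * n))
  hi <- ceiling(0.95 * n) - 1L
  if (lo > hi) integer() else lo:hi
}

cloud_band <- function(n) {
  lo <- 2L
  hi <- ceiling(0.15 * n) - 1L
  if (lo > hi) integer() else lo:hi
}

# Random ORF: ATG + non-stop codons + one stop codon.
random_orf <- function(len_bp) {
  codons <- max(3L, round(len_bp / 3))
  body <- sample(NON_STOP_CODONS, codons - 2L, replace = TRUE)
  paste0("ATG", paste(body, collapse = ""), sample(STOP_CODONS, 1L))
}

NON_STOP_CODONS <- local({
  b <- c("A", "C", "G", "T")
  setdiff(as.vector(outer(outer(b, b, paste0), b, paste0)), STOP_CODONS)
})

draw_gene_lengths <- function(k, mean_bp, sd_bp) {
  if (k == 0L) return(integer())
  sdlog <- sqrt(log(1 + (sd_bp / mean_bp)^2))
  meanlog <- log(mean_bp) - sdlog^2 / 2
  pmin(6000L, pmax(150L, round(stats::rlnorm(k, meanlog, sdlog))))
}

mutate_sites <- function(seq, rate) {
  len <- nchar(seq)
  n_mut <- rbinom(1L, len, rate)
  if (n_mut == 0L)
    return(list(seq = seq, pos = integer(), ref = character(),
                alt = character()))
  pos <- sort(sample.int(len, n_mut))
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  ref <- chars[pos]
  alt <- vapply(ref, function(b) sample(setdiff(DNA_BASES, b), 1L),
                character(1), USE.NAMES = FALSE)
  chars[pos] <- alt
  list(seq = paste(chars, collapse = ""), pos = pos, ref = ref, alt = alt)
}

# 2-bit encoding and rolling k-mer values (k = 15 fits exactly in a double).
DNA_CODE_LOOKUP <- local({
  v <- rep(NA_integer_, 256L)
  v[utf8ToInt("A")] <- 0L; v[utf8ToInt("C")] <- 1L
  v[utf8ToInt("G")] <- 2L; v[utf8ToInt("T")] <- 3L
  v
})

encode_dna <- function(seq) DNA_CODE_LOOKUP[utf8ToInt(seq)]

decode_dna <- function(codes) {
  paste(c("A", "C", "G", "T")[codes + 1L], collapse = "")
}

# numeric values of all k-mers of `codes`, forward and reverse complement
kmer_values <- function(codes, k = 15L) {
  L <- length(codes)
  if (L < k) return(numeric())
  n <- L - k + 1L
  fwd <- numeric(n); rc <- numeric(n)
  for (j in 0:(k - 1L)) {
    seg <- codes[(1L + j):(n + j)]
    fwd <- fwd + seg * 4^(k - 1L - j)
    rc <- rc + (3 - seg) * 4^j
  }
  c(fwd, rc)
}

# Vectorised binary search membership; avoids findInterval, which
# re-validates sortedness of the (large) haystack on every call.
in_sorted <- function(v, sorted) {
  n <- length(sorted)
  if (!n) return(rep(FALSE, length(v)))
  lo <- rep(1L, length(v))
  hi <- rep(n, length(v))
  repeat {
    act <- lo < hi
    if (!any(act)) break
    mid <- (lo + hi) %/% 2L
    smaller <- sorted[mid] < v
    lo <- ifelse(act & smaller, mid + 1L, lo)
    hi <- ifelse(act & !smaller, mid, hi)
  }
  sorted[lo] == v
}

CODON_CODES <- local({
  b <- c("A", "C", "G", "T")
  all <- as.matrix(expand.grid(0:3, 0:3, 0:3)[, 3:1])
  lab <- apply(all, 1L, function(r) paste(b[r + 1L], collapse = ""))
  list(non_stop = unname(all[!lab %in% STOP_CODONS, , drop = FALSE]),
       stop = unname(all[lab %in% STOP_CODONS, , drop = FALSE]))
})

# Build one gene whose every 15-mer (both strands) avoids `forbidden`
# (sorted numeric vector) and `extra_env` (k-mers of already accepted unique
# genes).  Codons are appended one at a time; a codon completing a forbidden
# 15-mer is redrawn.  Returns the sequence string or NULL on failure.
build_disjoint_gene <- function(len_bp, forbidden, extra_env, k = 15L,
                                codon_tries = 100L) {
  codons <- max(3L, round(len_bp / 3))
  codes <- integer(3L * codons)
  codes[1:3] <- c(0L, 3L, 2L)  # ATG
  new_vals <- function(pos) {
    # k-mers completed by bases pos-2..pos (ends at those positions)
    ends <- (pos - 2L):pos
    ends <- ends[ends >= k]
    if (!length(ends)) return(numeric())
    unlist(lapply(ends, function(e) {
      w <- codes[(e - k + 1L):e]
      c(sum(w * 4^((k - 1L):0)), sum((3 - w) * 4^(0:(k - 1L))))
    }))
  }
  ok_vals <- function(v) {
    if (!length(v)) return(TRUE)
    if (any(in_sorted(v, forbidden))) return(FALSE)
    !any(vapply(as.character(v), exists, logical(1), envir = extra_env,
                inherits = FALSE))
  }
  for (ci in 2:codons) {
    pool <- if (ci == codons) CODON_CODES$stop else CODON_CODES$non_stop
    pos <- 3L * ci
    placed <- FALSE
    for (try in seq_len(codon_tries)) {
      codes[(pos - 2L):pos] <- pool[sample.int(nrow(pool), 1L), ]
      if (ok_vals(new_vals(pos))) { placed <- TRUE; break }
    }
    if (!placed) return(NULL)
  }
  decode_dna(codes)
}

#' Simulate a genome collection with planted truth
#'
#' @param cfg a [sim_config()]
#' @param max_attempts rejection-sampling budget per unique gene
#' @return list with elements `genomes` (list of [annotated_genome()]) and
#'   `truth` (see Details)
#' @details The truth object records: `unique_tags` (per-genome planted
#'   unique gene tags), `carriage` (family to genome-id map), `families`
#'   (data.frame family/category/length), `gene_family` (gene tag to family
#'   map), `core_snps` (per genome, per core family substitution tables) and
#'   `distances` (pairwise core SNP distances over bi-allelic sites,
#'   recomputable by brute force from the emitted sequences).
#' @export
simulate_collection <- function(cfg, max_attempts = 50L) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, simulate_collection_impl(cfg, max_attempts))
}

simulate_collection_impl <- function(cfg, max_attempts) {
  n <- cfg$n_genomes
  genome_ids <- sprintf("SIM%02d", seq_len(n))

  fam <- data.frame(
    family = c(sprintf("core_%04d", seq_len(cfg$core_families)),
               sprintf("shell_%04d", seq_len(cfg$shell_families)),
               sprintf("cloud_%04d", seq_len(cfg$cloud_families))),
    category = rep(c("core", "shell", "cloud"),
                   c(cfg$core_families, cfg$shell_families,
                     cfg$cloud_families)),
    stringsAsFactors = FALSE)
  fam$length <- draw_gene_lengths(nrow(fam), cfg$gene_len_mean,
                                  cfg$gene_len_sd)
  fam_seq <- vapply(fam$length, random_orf, character(1))

  # carriage: core in all genomes; shell/cloud drawn inside their bands
  draw_carriers <- function(band, p) {
    repeat {
      k <- rbinom(1L, n, p)
      if (k %in% band) break
    }
    sort(sample.int(n, k))
  }
  carriage <- vector("list", nrow(fam))
  names(carriage) <- fam$family
  for (i in seq_len(nrow(fam))) {
    carriage[[i]] <- switch(fam$category[i],
      core = seq_len(n),
      shell = draw_carriers(shell_band(n), cfg$shell_carriage_prob),
      cloud = draw_carriers(cloud_band(n), cfg$cloud_carriage_prob))
  }

  # per-genome copies; core families diverge by point substitutions
  is_core <- fam$category == "core"
  copies <- vector("list", nrow(fam))   # list of per-carrier sequences
  core_snps <- lapply(genome_ids, function(g) list())
  names(core_snps) <- genome_ids
  for (i in seq_len(nrow(fam))) {
    carriers <- carriage[[i]]
    if (is_core[i] && cfg$core_snp_rate > 0) {
      per <- vector("character", length(carriers))
      for (j in seq_along(carriers)) {
        mut <- mutate_sites(fam_seq[i], cfg$core_snp_rate)
        per[j] <- mut$seq
        if (length(mut$pos))
          core_snps[[genome_ids[carriers[j]]]][[fam$family[i]]] <-
            data.frame(pos = mut$pos, ref = mut$ref, alt = mut$alt,
                       stringsAsFactors = FALSE)
      }
      copies[[i]] <- per
    } else {
      copies[[i]] <- rep(fam_seq[i], length(carriers))
    }
  }

  # strain-unique genes: no 15-mer shared with any other emitted gene
  # sequence (either strand), including the other planted unique genes
  unique_seqs <- vector("list", n)
  if (cfg$unique_per_genome > 0L) {
    pool <- unlist(copies, use.names = FALSE)
    forbidden <- sort(unique(unlist(
      lapply(pool, function(s) kmer_values(encode_dna(s))))))
    extra_env <- new.env(hash = TRUE, parent = emptyenv())
    ulen <- draw_gene_lengths(n * cfg$unique_per_genome,
                              cfg$gene_len_mean, cfg$gene_len_sd)
    idx <- 0L
    for (g in seq_len(n)) {
      seqs <- character(cfg$unique_per_genome)
      for (u in seq_len(cfg$unique_per_genome)) {
        idx <- idx + 1L
        cand <- NULL
        for (att in seq_len(max_attempts)) {
          cand <- build_disjoint_gene(ulen[idx], forbidden, extra_env)
          if (!is.null(cand)) break
        }
        if (is.null(cand))
          stop("could not fabricate a unique gene disjoint at the 15-mer ",
               "level after ", max_attempts,
               " attempts; try longer genes or fewer families",
               call. = FALSE)
        seqs[u] <- cand
        for (v in kmer_values(encode_dna(cand)))
          assign(as.character(v), TRUE, envir = extra_env)
      }
      unique_seqs[[g]] <- seqs
    }
  }

  # assemble genomes: shuffle genes, random strands, spacers, 1-5 contigs
  genomes <- vector("list", n)
  unique_tags <- setNames(vector("list", n), genome_ids)
  gene_family <- list()
  for (g in seq_len(n)) {
    gid <- genome_ids[g]
    fam_idx <- which(vapply(carriage, function(x) g %in% x, logical(1)))
    gene_seqs <- vapply(fam_idx, function(i)
      copies[[i]][match(g, carriage[[i]])], character(1))
    gene_fams <- fam$family[fam_idx]
    if (cfg$unique_per_genome > 0L) {
      gene_seqs <- c(gene_seqs, unique_seqs[[g]])
      gene_fams <- c(gene_fams,
                     sprintf("unique_%s_%02d", gid,
                             seq_len(cfg$unique_per_genome)))
    }
    ord <- sample(length(gene_seqs))
    gene_seqs <- gene_seqs[ord]
    gene_fams <- gene_fams[ord]
    tags <- sprintf("%s_%05d", gid, seq_along(gene_seqs))
    strands <- sample(c("+", "-"), length(gene_seqs), replace = TRUE)

    n_contigs <- sample(1:5, 1L)
    n_contigs <- min(n_contigs, length(gene_seqs))
    breaks <- sort(sample(seq_len(length(gene_seqs) - 1L),
                          n_contigs - 1L))
    contig_of <- findInterval(seq_along(gene_seqs) - 1L,
                              c(0L, breaks)) # 1-based contig index
    contig_seqs <- character(n_contigs)
    rows <- vector("list", length(gene_seqs))
    pos <- integer(n_contigs)
    for (ci in seq_len(n_contigs)) contig_seqs[ci] <- spacer()
    for (j in seq_along(gene_seqs)) {
      ci <- contig_of[j]
      s <- gene_seqs[j]
      placed <- if (strands[j] == "+") s else revcomp(s)
      start <- nchar(contig_seqs[ci]) + 1L
      contig_seqs[ci] <- paste0(contig_seqs[ci], placed, spacer())
      rows[[j]] <- data.frame(gene_tag = tags[j],
                              contig_id = sprintf("%s_ctg%d", gid, ci),
                              start = start,
                              end = start + nchar(s) - 1L,
                              strand = strands[j],
                              nt_seq = s, aa_seq = NA_character_,
                              annotation = gene_fams[j],
                              stringsAsFactors = FALSE)
    }
    genes <- do.call(rbind, rows)
    genes$aa_seq <- translate_cds_many(genes$nt_seq)
    contigs <- setNames(contig_seqs,
                        sprintf("%s_ctg%d", gid, seq_len(n_contigs)))
    genomes[[g]] <- annotated_genome(
      gid, contigs, genes,
      metadata = list(size_bp = sum(nchar(contigs)),
                      n_cds = nrow(genes)))
    unique_tags[[gid]] <- tags[grepl("^unique_", gene_fams)]
    gene_family[[gid]] <- data.frame(genome_id = gid, gene_tag = tags,
                                     family = gene_fams,
                                     stringsAsFactors = FALSE)
  }

  # realized family table including planted uniques
  fam_all <- rbind(fam[, c("family", "category", "length")],
                   do.call(rbind, lapply(seq_len(n), function(g)
                     if (cfg$unique_per_genome == 0L) NULL else
                     data.frame(family = sprintf("unique_%s_%02d",
                                                 genome_ids[g],
                                                 seq_len(cfg$unique_per_genome)),
                                category = "unique",
                                length = nchar(unique_seqs[[g]]),
                                stringsAsFactors = FALSE))))
  carriage_ids <- lapply(carriage, function(x) genome_ids[x])
  if (cfg$unique_per_genome > 0L)
    for (g in seq_len(n))
      for (u in seq_len(cfg$unique_per_genome))
        carriage_ids[[sprintf("unique_%s_%02d", genome_ids[g], u)]] <-
          genome_ids[g]

  dist <- truth_core_distances(copies[is_core], carriage[is_core], n)
  dimnames(dist) <- list(genome_ids, genome_ids)

  truth <- list(unique_tags = unique_tags,
                carriage = carriage_ids,
                families = fam_all,
                gene_family = do.call(rbind, gene_family),
                core_snps = core_snps,
                distances = dist,
                config = unclass(cfg))
  list(genomes = genomes, truth = truth)
}

spacer <- function() {
  paste(sample(DNA_BASES, sample(50:300, 1L), replace = TRUE),
        collapse = "")
}

# Pairwise Hamming distances over bi-allelic core columns, computed directly
# from the emitted per-genome copies (no alignment involved: core copies
# differ by substitutions only and share coordinates).
truth_core_distances <- function(core_copies, core_carriage, n) {
  D <- matrix(0L, n, n)
  for (i in seq_along(core_copies)) {
    if (length(core_carriage[[i]]) < n) next  # strict core only
    M <- do.call(rbind, strsplit(core_copies[[i]], "", fixed = TRUE))
    pres <- lapply(DNA_BASES, function(b)
      colSums(M == b) > 0L)
    n_alleles <- Reduce(`+`, lapply(pres, as.integer))
    keep <- which(n_alleles == 2L)
    if (!length(keep)) next
    K <- M[, keep, drop = FALSE]
    sim <- matrix(0L, n, n)
    for (b in DNA_BASES) {
      I <- (K == b) * 1L
      sim <- sim + tcrossprod(I)
    }
    D <- D + (length(keep) - sim)
  }
  diag(D) <- 0L
  storage.mode(D) <- "integer"
  D
}

#' Simulate a qPCR calibration table
#'
#' Ct values follow the linear standard-curve model
#' Ct = slope * log10(CFU) + intercept plus Gaussian noise.
#'
#' @param curve_slope Ct change per log10 CFU; must be negative
#'   (amplification means Ct decreases with template)
#' @param intercept Ct at log10 CFU = 0
#' @param levels log10 CFU levels of the dilution series
#' @param replicates replicates per level
#' @param noise_sd Ct noise standard deviation
#' @param seed RNG seed
#' @return data.frame with columns `sample`, `log10_cfu`, `ct`
#' @export
simulate_qpcr <- function(curve_slope, intercept, levels, replicates = 3L,
                          noise_sd = 0, seed = 1L) {
  if (!is.numeric(curve_slope) || curve_slope >= 0)
    stop("curve_slope must be negative", call. = FALSE)
  stopifnot(length(levels) >= 1L, replicates >= 1L, noise_sd >= 0)
  with_seed(seed, {
    lg <- rep(levels, each = replicates)
    rep_id <- rep(seq_len(replicates), times = length(levels))
    ct <- curve_slope * lg + intercept +
      if (noise_sd > 0) rnorm(length(lg), 0, noise_sd) else 0
    data.frame(sample = sprintf("std_lg%g_rep%d", lg, rep_id),
               log10_cfu = lg, ct = ct, stringsAsFactors = FALSE)
  })
}

#' Write a simulated collection to disk
#'
#' Per-genome FASTA + GFF3 plus a JSON truth file.
#'
#' @param sim result of [simulate_collection()]
#' @param dir output directory (created if needed)
#' @return invisibly, the directory
#' @export
write_collection <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (g in sim$genomes)
    write_genome(g, file.path(dir, paste0(g$genome_id, ".fna")),
                 file.path(dir, paste0(g$genome_id, ".gff")))
  truth <- sim$truth
  truth$distances <- as.data.frame(truth$distances)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}
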
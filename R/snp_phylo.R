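# Core-genome SNP calling, pairwise SNP distances, and neighbor-joining
# phylogeny.  Instead of whole-genome mapping, each genome's copy of every
# strict-core gene family is globally aligned (free terminal gaps) to the
# reference genome's copy; reference columns where every genome shows an
# unambiguous base are censused and the bi-allelic ones concatenated.

#' Call bi-allelic core-genome SNPs against a reference genome
#'
#' @param genomes list of [annotated_genome()] objects
#' @param matrix a [presence_absence_matrix()] over the same genomes
#' @param part a [partition()] of `matrix`
#' @param reference genome id used as coordinate backbone
#' @return object of class `core_snp_alignment`: per-genome concatenated
#'   allele strings plus a site table (family, reference position)
#' @export
call_core_snps <- function(genomes, matrix, part, reference) {
  stopifnot(inherits(matrix, "presence_absence_matrix"),
            inherits(part, "pangenome_partition"))
  genome_ids <- matrix$genome_ids
  if (!reference %in% genome_ids)
    stop("reference '", reference, "' not among genome ids", call. = FALSE)
  names(genomes) <- vapply(genomes, `[[`, character(1), "genome_id")
  if (!all(genome_ids %in% names(genomes)))
    stop("genome objects missing for some matrix columns", call. = FALSE)
  core_idx <- which(part$category == "core")
  if (!length(core_idx))
    stop("no core gene families; cannot call core SNPs", call. = FALSE)

  gene_seq <- function(gid, tag) {
    g <- genomes[[gid]]
    g$genes$nt_seq[match(tag, g$genes$gene_tag)]
  }

  allele_chunks <- rep(list(character()), length(genome_ids))
  names(allele_chunks) <- genome_ids

  site_fam <- character()
  site_pos <- integer()
  n <- length(genome_ids)
  for (ci in core_idx) {
    cl <- matrix$clusters[[ci]]
    mem <- cl$members
    # one member per genome: take the longest copy when paralogous
    if (!all(genome_ids %in% mem$genome_id)) {
      warning("core family ", cl$cluster_id,
              " missing from some genomes; skipped", call. = FALSE)
      next
    }
    seqs <- vapply(genome_ids, function(gid) {
      tags <- mem$gene_tag[mem$genome_id == gid]
      ss <- vapply(tags, function(t) gene_seq(gid, t), character(1))
      ss[which.max(nchar(ss))]
    }, character(1))
    ref_seq <- seqs[[reference]]
    ref_len <- nchar(ref_seq)
    # per-genome base at each reference position ('-' when gapped)
    base_mat <- matrix("-", nrow = n, ncol = ref_len)
    for (gi in seq_len(n)) {
      gid <- genome_ids[gi]
      if (gid == reference) {
        base_mat[gi, ] <- strsplit(ref_seq, "", fixed = TRUE)[[1]]
        next
      }
      aln <- nw_align_cpp(seqs[[gid]], ref_seq)
      a <- strsplit(aln[1], "", fixed = TRUE)[[1]]
      b <- strsplit(aln[2], "", fixed = TRUE)[[1]]
      refcol <- b != "-"
      base_mat[gi, ] <- a[refcol]
    }
    ok <- colSums(matrix(base_mat %in% c("A", "C", "G", "T"),
                         nrow = n)) == n
    if (!any(ok)) next
    sub <- base_mat[, ok, drop = FALSE]
    n_allele <- apply(sub, 2L, function(col) length(unique(col)))
    keep <- which(n_allele == 2L)
    if (!length(keep)) next
    pos_keep <- which(ok)[keep]
    for (gi in seq_len(n))
      allele_chunks[[gi]] <- c(allele_chunks[[gi]],
                               paste(sub[gi, keep], collapse = ""))
    site_fam <- c(site_fam, rep(cl$cluster_id, length(keep)))
    site_pos <- c(site_pos, pos_keep)
  }
  allele_str <- vapply(allele_chunks, paste, character(1), collapse = "")
  structure(list(genome_ids = genome_ids,
                 alleles = setNames(allele_str, genome_ids),
                 sites = data.frame(family = site_fam,
                                    ref_pos = site_pos,
                                    stringsAsFactors = FALSE),
                 reference = reference),
            class = "core_snp_alignment")
}

#' @export
print.core_snp_alignment <- function(x, ...) {
  cat(sprintf("<core_snp_alignment> %d genomes, %d bi-allelic sites (ref %s)\n",
              length(x$genome_ids), nrow(x$sites), x$reference))
  invisible(x)
}

#' Pairwise SNP distances
#'
#' Hamming distances between the concatenated bi-allelic allele strings.
#'
#' @param aln a [call_core_snps()] result
#' @return symmetric integer matrix over genome ids
#' @export
snp_distances <- function(aln) {
  stopifnot(inherits(aln, "core_snp_alignment"))
  n <- length(aln$genome_ids)
  D <- matrix(0L, n, n, dimnames = list(aln$genome_ids, aln$genome_ids))
  if (nrow(aln$sites) == 0L) return(D)
  M <- do.call(rbind, strsplit(unname(aln$alleles), "", fixed = TRUE))
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n)
      D[i, j] <- D[j, i] <- sum(M[i, ] != M[j, ])
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' The Saitou-Nei agglomeration with the standard Q criterion; ties in Q are
#' broken by the lowest (row, column) index pair and negative branch lengths
#' are clamped to zero.  Exact on additive matrices.
#'
#' @param d symmetric non-negative distance matrix with genome ids as
#'   dimnames (or a [snp_distances()] result)
#' @return an unrooted `ape::phylo` tree
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2L) stop("need at least 2 genomes", call. = FALSE)
  if (!isSymmetric(unname(d), tol = 1e-8) || any(d < 0))
    stop("distance matrix must be symmetric with non-negative entries",
         call. = FALSE)
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  # working copies; each active node is a newick fragment
  frag <- labels
  D <- d
  storage.mode(D) <- "double"
  bl <- function(x) sprintf("%.10g", max(0, x))
  while (nrow(D) > 3L) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    # lowest (row, column) pair among minima, scanning column-major upper pairs
    best <- c(NA_integer_, NA_integer_); bq <- Inf
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
      if (Q[i, j] < bq - 1e-12) { bq <- Q[i, j]; best <- c(i, j) }
    }
    i <- best[1L]; j <- best[2L]
    di <- 0.5 * D[i, j] + (r[i] - r[j]) / (2 * (m - 2))
    dj <- D[i, j] - di
    newfrag <- sprintf("(%s:%s,%s:%s)", frag[i], bl(di), frag[j], bl(dj))
    dnew <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    frag <- c(frag[keep], newfrag)
    D <- D2
  }
  if (nrow(D) == 3L) {
    # final star join of three nodes
    x <- 0.5 * (D[1, 2] + D[1, 3] - D[2, 3])
    y <- 0.5 * (D[1, 2] + D[2, 3] - D[1, 3])
    z <- 0.5 * (D[1, 3] + D[2, 3] - D[1, 2])
    nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", frag[1], bl(x), frag[2], bl(y),
                   frag[3], bl(z))
  } else {
    nwk <- sprintf("(%s:%s,%s:%s);", frag[1], bl(D[1, 2] / 2), frag[2],
                   bl(D[1, 2] / 2))
  }
  ape::read.tree(text = nwk)
}

#' Write a distance matrix as square TSV
#'
#' @param d distance matrix
#' @param path output path
#' @export
write_distance_tsv <- function(d, path) {
  df <- data.frame(genome = rownames(d), as.data.frame(d),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
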
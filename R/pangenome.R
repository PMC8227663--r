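# Pangenome construction: greedy centroid clustering of protein sequences,
# the presence/absence matrix, frequency-band partitioning, and gene
# accumulation (rarefaction) curves.

#' Construct a gene family (cluster)
#'
#' @param cluster_id family identifier
#' @param members data.frame with columns `genome_id`, `gene_tag` (>= 1 row
#'   for clusters produced by clustering; imported tables may carry
#'   incomplete member information)
#' @param representative gene tag of the representative (longest) member
#' @param avg_nt_len mean member nucleotide length (bp)
#' @param gene_name,annotation optional display fields
#' @return object of class `gene_cluster`
#' @export
gene_cluster <- function(cluster_id, members, representative,
                         avg_nt_len = NA_real_, gene_name = "",
                         annotation = "") {
  structure(list(cluster_id = cluster_id, members = members,
                 representative = representative, avg_nt_len = avg_nt_len,
                 gene_name = gene_name, annotation = annotation),
            class = "gene_cluster")
}

#' Construct a presence/absence matrix
#'
#' @param genome_ids ordered genome identifiers (matrix columns)
#' @param clusters list of [gene_cluster()] objects (matrix rows)
#' @param incidence logical matrix, clusters x genomes
#' @return object of class `presence_absence_matrix`
#' @export
presence_absence_matrix <- function(genome_ids, clusters, incidence) {
  stopifnot(is.matrix(incidence), is.logical(incidence),
            nrow(incidence) == length(clusters),
            ncol(incidence) == length(genome_ids))
  if (nrow(incidence) && any(rowSums(incidence) < 1L))
    stop("every gene family must be present in at least one genome",
         call. = FALSE)
  structure(list(genome_ids = genome_ids, clusters = clusters,
                 incidence = incidence),
            class = "presence_absence_matrix")
}

#' @export
print.presence_absence_matrix <- function(x, ...) {
  cat(sprintf("<presence_absence_matrix> %d families x %d genomes (%d presences)\n",
              nrow(x$incidence), ncol(x$incidence), sum(x$incidence)))
  invisible(x)
}

#' Cluster genes into families by greedy centroid clustering
#'
#' All genes of the collection are sorted by protein length (descending;
#' ties by genome id then gene tag) and assigned greedily: a gene joins the
#' earliest-founded centroid reaching `min_identity` global-alignment
#' identity (identical residues over alignment columns, terminal gaps
#' excluded) with a length ratio of at least 0.7, otherwise it founds a new
#' centroid.  The aligned region must additionally span at least 70% of the
#' shorter protein, so short chance overlaps between unrelated proteins
#' cannot satisfy the identity test.  This replaces the
#' CD-HIT/BLASTP/MCL cascade of pangenome
#' pipelines with a single deterministic pass while preserving the 90%
#' identity threshold semantics; externally produced presence/absence tables
#' can be imported with [read_presence_absence_csv()] instead.
#'
#' @param genomes list of [annotated_genome()] objects
#' @param min_identity minimum protein identity in (0, 1]; default 0.90
#' @param min_len_ratio minimum shorter/longer protein length ratio
#' @return list of [gene_cluster()] objects, in centroid founding order
#' @export
cluster_genes <- function(genomes, min_identity = 0.90,
                          min_len_ratio = 0.7) {
  stopifnot(length(genomes) >= 1L, min_identity > 0, min_identity <= 1)
  tab <- do.call(rbind, lapply(genomes, function(g) {
    if (!nrow(g$genes)) return(NULL)
    data.frame(genome_id = g$genome_id, gene_tag = g$genes$gene_tag,
               aa = g$genes$aa_seq, nt_len = nchar(g$genes$nt_seq),
               stringsAsFactors = FALSE)
  }))
  if (is.null(tab) || !nrow(tab))
    stop("no genes found in the supplied genomes", call. = FALSE)
  ord <- order(-nchar(tab$aa), tab$genome_id, tab$gene_tag)
  tab <- tab[ord, , drop = FALSE]
  assign <- greedy_cluster_cpp(tab$aa, min_identity, min_len_ratio)
  ids <- sprintf("group_%04d", seq_len(max(assign)))
  lapply(seq_len(max(assign)), function(k) {
    rows <- tab[assign == k, , drop = FALSE]
    gene_cluster(ids[k],
                 members = data.frame(genome_id = rows$genome_id,
                                      gene_tag = rows$gene_tag,
                                      stringsAsFactors = FALSE),
                 representative = rows$gene_tag[1L],  # longest member
                 avg_nt_len = mean(rows$nt_len))
  })
}

#' Build the presence/absence matrix from gene families
#'
#' Paralogs (several members of one family in the same genome) collapse to
#' a single presence.
#'
#' @param clusters list of [gene_cluster()] objects
#' @param genome_ids ordered genome identifiers; every member's genome must
#'   appear here
#' @return a [presence_absence_matrix()]
#' @export
build_matrix <- function(clusters, genome_ids) {
  incidence <- matrix(FALSE, nrow = length(clusters),
                      ncol = length(genome_ids),
                      dimnames = list(vapply(clusters, `[[`, character(1),
                                             "cluster_id"),
                                      genome_ids))
  for (i in seq_along(clusters)) {
    gids <- unique(clusters[[i]]$members$genome_id)
    unknown <- setdiff(gids, genome_ids)
    if (length(unknown))
      stop("cluster ", clusters[[i]]$cluster_id,
           " has member in unknown genome ", unknown[1L], call. = FALSE)
    incidence[i, gids] <- TRUE
  }
  presence_absence_matrix(genome_ids, clusters, incidence)
}

#' Partition a pangenome into frequency compartments
#'
#' Families carried by exactly one genome are `unique` (checked before the
#' fractional bands); the remainder are assigned by carriage fraction k/N:
#' core >= 0.99, soft-core [0.95, 0.99), shell [0.15, 0.95), cloud (0, 0.15).
#' The cloud lower bound is treated as exclusive-zero so the five categories
#' are exhaustive for any collection size.
#'
#' @param matrix a [presence_absence_matrix()]
#' @return object of class `pangenome_partition`: per-family category factor
#'   plus a count summary
#' @export
partition <- function(matrix) {
  stopifnot(inherits(matrix, "presence_absence_matrix"))
  n <- length(matrix$genome_ids)
  stopifnot(n >= 1L)
  k <- rowSums(matrix$incidence)
  frac <- k / n
  category <- ifelse(k == 1L, "unique",
              ifelse(frac >= 0.99, "core",
              ifelse(frac >= 0.95, "soft_core",
              ifelse(frac >= 0.15, "shell", "cloud"))))
  category <- factor(category,
                     levels = c("unique", "core", "soft_core", "shell",
                                "cloud"))
  structure(list(category = setNames(category, rownames(matrix$incidence)),
                 counts = table(category),
                 n_genomes = n),
            class = "pangenome_partition")
}

#' @export
print.pangenome_partition <- function(x, ...) {
  cat("<pangenome_partition>\n")
  print(x$counts)
  invisible(x)
}

#' Strain-unique gene families of a target genome
#'
#' @param matrix a [presence_absence_matrix()]
#' @param target genome id
#' @return list of [gene_cluster()] carried by the target and no other
#'   genome, ordered by representative gene tag
#' @export
unique_genes <- function(matrix, target) {
  stopifnot(inherits(matrix, "presence_absence_matrix"))
  if (!target %in% matrix$genome_ids)
    stop("unknown genome id '", target, "'", call. = FALSE)
  k <- rowSums(matrix$incidence)
  hit <- which(k == 1L & matrix$incidence[, target])
  out <- matrix$clusters[hit]
  reps <- vapply(out, function(cl)
    as.character(cl$representative %||% cl$cluster_id), character(1))
  out[order(reps)]
}

#' Gene accumulation (rarefaction) curve
#'
#' For random genome orderings, the number of families seen in at least one
#' of the first m genomes (total) and in all of the first m genomes
#' (conserved), averaged over orderings.  A persistently rising total with a
#' falling conserved count is the signature of an open pangenome.
#'
#' @param matrix a [presence_absence_matrix()]
#' @param n_orderings number of random orderings (ignored when `exhaustive`)
#' @param seed RNG seed for the orderings
#' @param exhaustive enumerate all N! orderings instead of sampling (only
#'   sensible for small collections)
#' @return data.frame with columns `m`, `mean_total`, `mean_conserved`
#' @export
rarefaction <- function(matrix, n_orderings = 100L, seed = 1L,
                        exhaustive = FALSE) {
  stopifnot(inherits(matrix, "presence_absence_matrix"), n_orderings >= 1L)
  inc <- matrix$incidence
  n <- ncol(inc)
  one_ordering <- function(ord) {
    m <- inc[, ord, drop = FALSE]
    any_cum <- t(apply(m, 1L, cummax))
    all_cum <- t(apply(m, 1L, cummin))
    cbind(total = colSums(any_cum), conserved = colSums(all_cum))
  }
  orderings <- if (exhaustive) {
    perms <- all_permutations(n)
  } else {
    with_seed(seed, replicate(n_orderings, sample.int(n), simplify = FALSE))
  }
  acc <- Reduce(`+`, lapply(orderings, one_ordering))
  acc <- acc / length(orderings)
  data.frame(m = seq_len(n), mean_total = acc[, "total"],
             mean_conserved = acc[, "conserved"])
}

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    rest <- all_permutations(n - 1L)
    out <- c(out, lapply(rest, function(p) c(i, setdiff(seq_len(n), i)[p])))
  }
  out
}

#' Write the partition summary as TSV
#'
#' @param part a [partition()] result
#' @param path output TSV (category, count, fraction)
#' @return invisibly, the data.frame written
#' @export
write_partition_summary <- function(part, path) {
  df <- data.frame(category = names(part$counts),
                   count = as.integer(part$counts),
                   fraction = as.numeric(part$counts) / sum(part$counts))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
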
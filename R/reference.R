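# Reduced "tRNA genome" construction: gene validation, Euclidean-distance
# clustering of near-identical isodecoders, per-family consensus compilation.

.RNA_ALPHABET <- c("A", "C", "G", "U")

#' Validate a table of tRNA genes
#'
#' Genes are genomic-predicted tRNA sequences (no modifications), 60-100 nt,
#' over the RNA alphabet A/C/G/U. DNA input (T) is accepted and transcribed
#' when `convert_t = TRUE`.
#'
#' @param genes tibble with columns `id`, `sequence` and optionally
#'   `isoacceptor` (amino acid + anticodon token, e.g. `"Ala-AGC"`).
#' @param convert_t replace T by U before validation (default `TRUE`).
#' @return the validated tibble (sequences uppercased, T converted).
#' @export
validate_genes <- function(genes, convert_t = TRUE) {
  genes <- as_tibble(genes)
  if (nrow(genes) == 0) stop("no tRNA genes supplied", call. = FALSE)
  stopifnot(all(c("id", "sequence") %in% names(genes)))
  if (anyDuplicated(genes$id)) stop("duplicated gene ids", call. = FALSE)
  genes$sequence <- toupper(genes$sequence)
  if (convert_t) genes$sequence <- gsub("T", "U", genes$sequence, fixed = TRUE)
  len <- nchar(genes$sequence)
  bad_len <- which(len < 60 | len > 100)
  if (length(bad_len)) {
    stop("gene(s) with length outside [60, 100]: ",
         paste(genes$id[bad_len], collapse = ", "), call. = FALSE)
  }
  ok <- vapply(strsplit(genes$sequence, ""), function(x)
    all(x %in% .RNA_ALPHABET), logical(1))
  if (!all(ok)) {
    stop("gene(s) with characters outside {A,C,G,U}: ",
         paste(genes$id[!ok], collapse = ", "), call. = FALSE)
  }
  if (!"isoacceptor" %in% names(genes)) genes$isoacceptor <- NA_character_
  genes
}

#' Read tRNA genes from FASTA
#'
#' The description line may carry an isoacceptor token such as `Ala-AGC`,
#' which is extracted when present.
#'
#' @param path FASTA file of predicted tRNA gene sequences (DNA or RNA).
#' @return validated gene tibble (`id`, `sequence`, `isoacceptor`).
#' @export
read_trna_genes <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  iso <- regmatches(names(ss),
                    regexpr("[A-Z][a-z]{2}-[ACGTU]{3}", names(ss)))
  iso_full <- rep(NA_character_, length(ss))
  has <- grepl("[A-Z][a-z]{2}-[ACGTU]{3}", names(ss))
  iso_full[has] <- iso
  validate_genes(tibble(id = ids, sequence = unname(as.character(ss)),
                        isoacceptor = iso_full))
}

# Global Needleman-Wunsch (match 1 / mismatch 0 / gap -1) via Biostrings;
# returns the two gapped strings.
.align_pair <- function(a, b) {
  sub <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = 0,
                                                  baseOnly = FALSE)
  pa <- Biostrings::pairwiseAlignment(
    gsub("U", "T", a), gsub("U", "T", b), type = "global",
    substitutionMatrix = sub, gapOpening = 0, gapExtension = 1
  )
  al <- c(as.character(Biostrings::alignedPattern(pa)),
          as.character(Biostrings::alignedSubject(pa)))
  gsub("T", "U", al)
}

#' Euclidean distance between two tRNA sequences
#'
#' Sequences are globally aligned (Needleman-Wunsch, match 1 / mismatch 0 /
#' gap -1) and each aligned column one-hot encoded over \{A,C,G,U,gap\}.
#' Under this encoding two columns contribute 0 when identical and 2 to the
#' squared distance otherwise, so the distance is `sqrt(2 * n_diff)`.
#'
#' @param a,b RNA sequences (character scalars).
#' @return non-negative numeric distance.
#' @export
#' @examples
#' seq_distance("ACGU", "ACGU")   # 0
#' seq_distance(strrep("A", 76), paste0(strrep("A", 75), "C"))  # sqrt(2)
seq_distance <- function(a, b) {
  al <- .align_pair(a, b)
  x <- strsplit(al[1], "")[[1]]
  y <- strsplit(al[2], "")[[1]]
  sqrt(2 * sum(x != y))
}

#' Pairwise distance matrix for a gene set
#'
#' @param genes validated gene tibble.
#' @return symmetric numeric matrix with gene ids as dimnames.
#' @export
gene_distance_matrix <- function(genes) {
  genes <- validate_genes(genes)
  n <- nrow(genes)
  d <- matrix(0, n, n, dimnames = list(genes$id, genes$id))
  if (n == 1) return(d)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- seq_distance(genes$sequence[i], genes$sequence[j])
    }
  }
  d
}

#' Cluster tRNA genes into sequence families
#'
#' Single-linkage closure at a Euclidean-distance cutoff: any two genes at
#' distance <= cutoff (directly or through intermediates) share a family.
#' The default cutoff 2 merges genes that differ by at most two substitutions
#' (`sqrt(2 * 2) ~ 2`), i.e. isodecoders differing by a few SNPs.
#'
#' @param genes validated gene tibble.
#' @param cutoff non-negative distance cutoff (default 2).
#' @return list of character vectors of gene ids, ordered by first
#'   appearance in the input; every gene occurs in exactly one cluster.
#' @export
cluster_genes <- function(genes, cutoff = 2) {
  stopifnot(is.numeric(cutoff), cutoff >= 0)
  genes <- validate_genes(genes)
  if (nrow(genes) == 1) return(list(genes$id))
  d <- gene_distance_matrix(genes)
  hc <- hclust(stats::as.dist(d), method = "single")
  grp <- cutree(hc, h = cutoff)
  ord <- unique(grp[genes$id])  # clusters in order of first member
  lapply(ord, function(g) genes$id[grp[genes$id] == g])
}

#' Family reference constructor
#'
#' @param family_id family identifier.
#' @param consensus consensus RNA sequence.
#' @param members character vector of member gene ids.
#' @param numbering optional tibble (`index` 0-based, `label` Sprinzl), as
#'   filled by [assign_sprinzl()].
#' @return object of class `family_reference`.
#' @export
family_reference <- function(family_id, consensus, members,
                             numbering = NULL) {
  stopifnot(is.character(family_id), length(family_id) == 1,
            is.character(consensus), length(consensus) == 1,
            length(members) >= 1)
  if (!is.null(numbering)) {
    stopifnot(nrow(numbering) == nchar(consensus),
              !anyDuplicated(numbering$index), !anyDuplicated(numbering$label))
  }
  structure(
    list(family_id = family_id, consensus = consensus,
         members = as.character(members), numbering = numbering),
    class = "family_reference"
  )
}

#' @export
print.family_reference <- function(x, ...) {
  cat("<family_reference> ", x$family_id, ": ", nchar(x$consensus),
      " nt, ", length(x$members), " member(s)",
      if (is.null(x$numbering)) " (unnumbered)" else " (Sprinzl-numbered)",
      "\n", sep = "")
  invisible(x)
}

#' Compile the consensus sequence of a gene cluster
#'
#' Members are center-star aligned against the longest member (global
#' Needleman-Wunsch, match 1 / mismatch 0 / gap -1); insertions of a member
#' relative to that reference are dropped with a warning. Each column takes
#' the strict-majority base; ties are broken by the base of the first member
#' in input order, with a warning. Columns whose majority is a gap are
#' removed.
#'
#' @param cluster validated gene tibble (the members of one cluster).
#' @param family_id id for the resulting family; default derived from the
#'   first member.
#' @return a [family_reference()] (numbering unassigned).
#' @export
build_consensus <- function(cluster, family_id = NULL) {
  cluster <- validate_genes(cluster)
  if (is.null(family_id)) family_id <- paste0("fam_", cluster$id[1])
  n <- nrow(cluster)
  ref_i <- which.max(nchar(cluster$sequence))
  ref <- cluster$sequence[ref_i]
  L <- nchar(ref)
  mat <- matrix("-", nrow = n, ncol = L)
  for (i in seq_len(n)) {
    if (cluster$sequence[i] == ref) {
      mat[i, ] <- strsplit(ref, "")[[1]]
      next
    }
    al <- .align_pair(ref, cluster$sequence[i])
    rcols <- strsplit(al[1], "")[[1]]
    mcols <- strsplit(al[2], "")[[1]]
    if (any(rcols == "-")) {
      warning("member '", cluster$id[i], "' has insertion(s) relative to ",
              "the family reference; inserted bases dropped", call. = FALSE)
      keep <- rcols != "-"
      mcols <- mcols[keep]
    }
    mat[i, ] <- mcols
  }
  cons <- character(L)
  tie_cols <- integer(0)
  for (j in seq_len(L)) {
    tab <- table(mat[, j])
    top <- names(tab)[tab == max(tab)]
    if (length(top) > 1) {
      tie_cols <- c(tie_cols, j)
      # first-listed member's base wins (determinism)
      first_base <- mat[1, j]
      cons[j] <- if (first_base %in% top) first_base else top[1]
    } else {
      cons[j] <- top
    }
  }
  if (length(tie_cols)) {
    warning("consensus tie at column(s) ", paste(tie_cols, collapse = ", "),
            " of family '", family_id, "'; resolved to the first member's base",
            call. = FALSE)
  }
  cons <- cons[cons != "-"]
  family_reference(family_id, paste(cons, collapse = ""), cluster$id)
}

#' Build the full reduced tRNA reference
#'
#' Clusters genes, compiles one consensus per cluster and assigns Sprinzl
#' numbering. Family ids are taken from the isoacceptor label of the first
#' member when available (made unique), else from the first member id.
#'
#' @inheritParams cluster_genes
#' @param template a [sprinzl_template()].
#' @return named list of numbered [family_reference()] objects.
#' @export
build_reference <- function(genes, cutoff = 2, template = sprinzl_template()) {
  genes <- validate_genes(genes)
  clusters <- cluster_genes(genes, cutoff)
  ids <- vapply(clusters, function(m) {
    iso <- genes$isoacceptor[match(m[1], genes$id)]
    if (is.na(iso)) m[1] else gsub("-", "_", iso)
  }, character(1))
  ids <- make.unique(ids, sep = "_")
  fams <- vector("list", length(clusters))
  for (k in seq_along(clusters)) {
    fam <- build_consensus(genes[genes$id %in% clusters[[k]], , drop = FALSE],
                           family_id = ids[k])
    fams[[k]] <- assign_sprinzl(fam, template)
  }
  names(fams) <- ids
  fams
}

#' Write family consensus FASTA and numbering table
#'
#' @param families list of numbered [family_reference()] objects.
#' @param fasta,table output paths (either may be `NULL` to skip).
#' @return invisibly, the numbering table (family, index, label, base).
#' @export
write_reference <- function(families, fasta = NULL, table = NULL) {
  stopifnot(length(families) >= 1)
  tab <- bind_rows(lapply(families, function(f) {
    tibble(family = f$family_id, index = f$numbering$index,
           label = f$numbering$label,
           base = strsplit(f$consensus, "")[[1]])
  }))
  if (!is.null(fasta)) {
    seqs <- Biostrings::BStringSet(
      setNames(vapply(families, `[[`, "", "consensus"),
               vapply(families, `[[`, "", "family_id")))
    Biostrings::writeXStringSet(seqs, fasta)
  }
  if (!is.null(table)) readr::write_tsv(tab, table)
  invisible(tab)
}

# Consensus base lookup: tibble(family, position (1-based), label, base)
.family_bases <- function(families) {
  bind_rows(lapply(families, function(f) {
    tibble(family = f$family_id,
           position = seq_len(nchar(f$consensus)),
           label = if (is.null(f$numbering)) as.character(seq_len(nchar(f$consensus))) else f$numbering$label,
           base = strsplit(f$consensus, "")[[1]])
  }))
}
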
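#' Sequence alignments of haploid sequences
#'
#' An alignment is stored as a list with a character matrix `seqs` (one row per
#' sequence, one column per site, uppercase bases over `A C G T - N`), the
#' sequence ids as `ids` (also the rownames of `seqs`), the sample size `n` and
#' the alignment length `k` in bp.
#'
#' @param seqs character vector of equal-length sequence strings, or a
#'   character matrix with one row per sequence and one column per site.
#' @param ids unique sequence labels; defaults to names of `seqs` or
#'   `rownames(seqs)`.
#' @return An object of class `"dna_alignment"`.
#' @examples
#' aln <- dna_alignment(c(a = "ACGT", b = "ACGA"))
#' aln$n; aln$k
#' @export
dna_alignment <- function(seqs, ids = NULL) {
  if (is.matrix(seqs)) {
    mat <- seqs
    if (is.null(ids)) ids <- rownames(mat)
  } else {
    if (is.null(ids)) ids <- names(seqs)
    seqs <- as.character(seqs)
    if (length(seqs) == 0L) stop("empty alignment: no sequences")
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1L) {
      stop("alignment error: sequences have unequal lengths (",
           paste(unique(lens), collapse = ", "), ")")
    }
    if (lens[1] == 0L) stop("empty alignment: zero-length sequences")
    mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  }
  if (is.null(ids)) ids <- paste0("seq", seq_len(nrow(mat)))
  ids <- as.character(ids)
  if (anyDuplicated(ids)) {
    stop("input error: duplicate sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (length(ids) != nrow(mat)) stop("ids do not match number of sequences")
  mat <- toupper(mat)
  mat[mat == "U"] <- "T"
  bad <- setdiff(unique(as.vector(mat)), c("A", "C", "G", "T", "-", "N"))
  if (length(bad) > 0L) {
    stop("input error: unsupported characters in sequences: ",
         paste(bad, collapse = ", "),
         " (only A, C, G, T, '-' and N are accepted;",
         " resolve other IUPAC ambiguity codes before import)")
  }
  dimnames(mat) <- list(ids, NULL)
  structure(list(ids = ids, seqs = mat, n = nrow(mat), k = ncol(mat)),
            class = "dna_alignment")
}

#' @export
print.dna_alignment <- function(x, ...) {
  cat("DNA alignment:", x$n, "sequences x", x$k, "bp\n")
  tab <- table(factor(as.vector(x$seqs), levels = c("A", "C", "G", "T", "-", "N")))
  comp <- round(100 * tab / sum(tab), 1)
  cat("Composition (%):", paste(names(comp), comp, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Read a FASTA alignment
#'
#' Reads aligned sequences from a FASTA file. Headers are `>` lines; the id is
#' the header up to the first whitespace; sequence lines may wrap. Sequences
#' are uppercased and `U` is mapped to `T`. All records must have equal length.
#' Ambiguity codes other than `N` are rejected.
#'
#' @param path path to a FASTA file.
#' @return A [dna_alignment()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("input error: file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("input error: empty FASTA file: ", path)
  hdr <- grepl("^>", lines)
  if (!hdr[1]) stop("input error: not a FASTA file (no '>' header): ", path)
  rec <- cumsum(hdr)
  ids <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
  seqs <- vapply(split(lines[!hdr], rec[!hdr]),
                 function(x) paste(gsub("\\s", "", x), collapse = ""), "")
  if (length(seqs) != length(ids) || any(!nzchar(seqs))) {
    stop("input error: FASTA record with no sequence data")
  }
  dna_alignment(unname(seqs), ids = ids)
}

#' Write a FASTA alignment
#'
#' Writes the canonical dialect read by [read_fasta()]: uppercase, one
#' unwrapped sequence line per record. `read_fasta()` followed by
#' `write_fasta()` round-trips canonical files byte-for-byte.
#'
#' @param aln a [dna_alignment()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(aln, path) {
  stopifnot(inherits(aln, "dna_alignment"))
  seqs <- apply(aln$seqs, 1, paste, collapse = "")
  writeLines(paste0(">", aln$ids, "\n", seqs), path, sep = "\n")
  invisible(path)
}

#' Remove alignment columns containing gaps
#'
#' Complete-deletion treatment of indels: every column in which any sequence
#' carries `-` is removed, so downstream statistics see a gap-free alignment.
#' Idempotent; column order is preserved.
#'
#' @param aln a [dna_alignment()].
#' @return A gap-free [dna_alignment()] (k possibly reduced).
#' @export
exclude_indels <- function(aln) {
  stopifnot(inherits(aln, "dna_alignment"))
  gap_col <- apply(aln$seqs == "-", 2, any)
  if (all(gap_col)) stop("no sites remain after indel exclusion")
  if (!any(gap_col)) return(aln)
  dna_alignment(aln$seqs[, !gap_col, drop = FALSE], ids = aln$ids)
}

#' Collapse an alignment to haplotypes
#'
#' Identical sequences are merged into haplotypes with counts. Sequences are
#' compared literally, including `N` (no inferential merging), so the result is
#' deterministic. Apply [exclude_indels()] first for gapped alignments.
#'
#' @param aln a [dna_alignment()].
#' @return An object of class `"haplotype_table"`: `haplotypes` (distinct
#'   sequence strings), `counts`, `members` (ids per haplotype), `h`, `n`.
#' @examples
#' ht <- haplotypes(dna_alignment(c("ACGT", "ACGT", "ACGA")))
#' ht$h          # 2
#' ht$counts     # 2 1
#' @export
haplotypes <- function(aln) {
  stopifnot(inherits(aln, "dna_alignment"))
  key <- apply(aln$seqs, 1, paste, collapse = "")
  grp <- split(aln$ids, factor(key, levels = unique(key)))
  structure(list(haplotypes = names(grp),
                 counts = lengths(grp),
                 members = grp,
                 h = length(grp),
                 n = aln$n),
            class = "haplotype_table")
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat("Haplotype table:", x$h, "haplotypes among", x$n, "sequences\n")
  cat("Counts:", paste(sort(unname(x$counts), decreasing = TRUE), collapse = " "), "\n")
  invisible(x)
}

# Subset an alignment by sequence id or index (internal convenience).
subset_alignment <- function(aln, which) {
  if (is.character(which)) {
    miss <- setdiff(which, aln$ids)
    if (length(miss)) stop("unknown sequence ids: ", paste(miss, collapse = ", "))
    which <- match(which, aln$ids)
  }
  dna_alignment(aln$seqs[which, , drop = FALSE], ids = aln$ids[which])
}
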
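#' Sequence alignments
#'
#' A `dna_alignment` is a character matrix of single upper-case characters over
#' `{A,C,G,T,N,-}` with one row per sample (row names are the sample ids) and
#' one column per aligned site. All user-facing functions in tideclock accept
#' this class; build one from a FASTA file with [read_alignment()] or from a
#' character vector of sequences with `dna_alignment()`.
#'
#' @param seqs named character vector of equal-length sequence strings, or a
#'   character matrix of single characters with row names.
#' @param ids sample identifiers; defaults to the names of `seqs`.
#'
#' @return A `dna_alignment` object (character matrix with class attribute).
#' @examples
#' aln <- dna_alignment(c(a = "ACGT", b = "ACGA"))
#' n_samples(aln); n_sites(aln)
#' @export
dna_alignment <- function(seqs, ids = names(seqs)) {
  if (is.matrix(seqs)) {
    m <- seqs
    if (!is.null(ids)) rownames(m) <- ids
  } else {
    if (!is.character(seqs) || length(seqs) < 1L) {
      abort("`seqs` must be a non-empty character vector or matrix")
    }
    if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1L) {
      abort("alignment error: sequences have unequal lengths")
    }
    if (lens[1] == 0L) abort("alignment error: zero-length sequences")
    m <- do.call(rbind, strsplit(toupper(seqs), ""))
    rownames(m) <- ids
  }
  m[] <- toupper(m)
  if (anyDuplicated(rownames(m))) abort("input error: duplicate sequence ids")
  bad <- setdiff(unique(as.vector(m)), c("A", "C", "G", "T", "N", "-"))
  if (length(bad)) {
    # common IUPAC ambiguity codes are tolerated but treated as missing
    m[m %in% bad] <- "N"
  }
  structure(m, class = c("dna_alignment", "matrix", "array"))
}

#' @rdname dna_alignment
#' @param x a `dna_alignment`.
#' @export
n_samples <- function(x) nrow(x)

#' @rdname dna_alignment
#' @export
n_sites <- function(x) ncol(x)

#' @export
print.dna_alignment <- function(x, ...) {
  cat(sprintf("<dna_alignment> %d sequences x %d sites\n", nrow(x), ncol(x)))
  show <- head(rownames(x), 5)
  for (id in show) {
    s <- paste(x[id, seq_len(min(ncol(x), 50))], collapse = "")
    cat(sprintf("  %-12s %s%s\n", id, s, if (ncol(x) > 50) "..." else ""))
  }
  if (nrow(x) > 5) cat(sprintf("  ... and %d more\n", nrow(x) - 5))
  invisible(x)
}

#' @export
as_tibble.dna_alignment <- function(x, ...) {
  tibble(id = rownames(x), sequence = apply(x, 1, paste, collapse = ""))
}

#' Read an aligned FASTA file
#'
#' Reads a (wrapped or single-line) FASTA file of pre-aligned sequences.
#' Sequences are upper-cased; gaps are preserved.
#'
#' @param path path to a FASTA file.
#' @return A [dna_alignment].
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  recs <- ape::read.FASTA(path)
  if (length(recs) == 0L) abort("input error: FASTA file contains no records")
  lens <- lengths(recs)
  if (length(unique(lens)) != 1L) {
    abort("alignment error: sequences have unequal lengths; input must be aligned")
  }
  m <- toupper(as.character(as.matrix(recs)))
  dna_alignment(m, ids = names(recs))
}

#' @rdname read_alignment
#' @param aln a [dna_alignment].
#' @export
write_alignment <- function(aln, path) {
  seqs <- apply(aln, 1, paste, collapse = "")
  lines <- character(0)
  for (i in seq_along(seqs)) {
    lines <- c(lines, paste0(">", rownames(aln)[i]), seqs[[i]])
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read sample metadata
#'
#' Reads a CSV with header `id,locality,lat,lon` giving the sampling locality
#' and coordinates (decimal degrees) for each individual.
#'
#' @param path path to the metadata CSV.
#' @return A tibble with columns `id`, `locality`, `lat`, `lon`.
#' @export
read_metadata <- function(path) {
  md <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  validate_metadata(md)
}

validate_metadata <- function(md) {
  need <- c("id", "locality", "lat", "lon")
  if (!all(need %in% names(md))) {
    abort("input error: metadata must have columns id, locality, lat, lon")
  }
  if (anyDuplicated(md$id)) abort("input error: duplicate ids in metadata")
  if (any(abs(md$lat) > 90) || any(abs(md$lon) > 180)) {
    abort("input error: coordinates outside valid range")
  }
  as_tibble(md[, need])
}

#' Collapse identical sequences into haplotypes
#'
#' Identical sequences are collapsed into haplotypes in first-seen order. By
#' default two sequences belong to one haplotype only when they are
#' string-identical (including `N`/`-`); with `match_resolved = TRUE`,
#' sequences are merged when their resolved (non-`N`, non-gap) positions agree
#' and the sequences are compatible at every site.
#'
#' @param aln a [dna_alignment].
#' @param meta optional metadata tibble (see [read_metadata()]); when supplied,
#'   per-locality counts are attached as a nested tibble column.
#' @param match_resolved collapse on resolved sites rather than exact strings.
#' @return A tibble with columns `haplotype` (id, `H1`, `H2`, ... in
#'   first-seen order), `count`, `members` (list of sample ids), `sequence`,
#'   and, when `meta` is given, `locality_counts` (list of tibbles).
#' @examples
#' aln <- dna_alignment(c(a = "ACGT", b = "ACGT", c = "ACGA"))
#' collapse_haplotypes(aln)
#' @export
collapse_haplotypes <- function(aln, meta = NULL, match_resolved = FALSE) {
  stopifnot(inherits(aln, "dna_alignment"))
  seqs <- apply(aln, 1, paste, collapse = "")
  ids <- rownames(aln)
  if (!is.null(meta)) {
    meta <- validate_metadata(meta)
    missing_ids <- setdiff(ids, meta$id)
    if (length(missing_ids)) {
      abort(sprintf("input error: metadata missing ids: %s",
                    paste(head(missing_ids, 5), collapse = ", ")))
    }
  }
  if (!match_resolved) {
    key <- seqs
  } else {
    # merge sequences whose resolved positions agree; ambiguous sites are
    # wildcards. Greedy first-seen assignment.
    key <- character(length(seqs))
    reps <- list()
    for (i in seq_along(seqs)) {
      si <- aln[i, ]
      hit <- NA_integer_
      for (j in seq_along(reps)) {
        rj <- reps[[j]]
        res <- si != "N" & si != "-" & rj != "N" & rj != "-"
        if (all(si[res] == rj[res])) { hit <- j; break }
      }
      if (is.na(hit)) {
        reps[[length(reps) + 1L]] <- si
        hit <- length(reps)
      }
      key[i] <- paste0("grp", hit)
    }
  }
  first_seen <- !duplicated(key)
  levels_seen <- key[first_seen]
  grp <- match(key, levels_seen)
  out <- tibble(
    haplotype = paste0("H", sort(unique(grp))),
    count = as.integer(tabulate(grp)),
    members = split(ids, grp),
    sequence = seqs[first_seen]
  )
  if (!is.null(meta)) {
    loc <- setNames(meta$locality, meta$id)
    out$locality_counts <- lapply(out$members, function(m) {
      tb <- table(loc[m])
      tibble(locality = names(tb), count = as.integer(tb))
    })
  }
  attr(out, "n") <- length(ids)
  out
}

#' Representative alignment of haplotypes
#'
#' One representative sequence per haplotype, named by haplotype id.
#'
#' @param ht a haplotype table from [collapse_haplotypes()].
#' @return A [dna_alignment] of the representative sequences.
#' @export
haplotype_alignment <- function(ht) {
  dna_alignment(setNames(ht$sequence, ht$haplotype))
}
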
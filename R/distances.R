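#' Pairwise genetic distances
#'
#' Computes a symmetric matrix of pairwise distances between all sequences of
#' an alignment under pairwise deletion: at each pair, only sites where both
#' bases are in `{A,C,G,T}` are compared.
#'
#' Models:
#' \describe{
#'   \item{`raw_differences`}{number of differing resolved sites (units: sites).}
#'   \item{`p_distance`}{raw differences divided by compared sites
#'     (substitutions/site, uncorrected).}
#'   \item{`TN93`}{Tamura-Nei closed-form distance (substitutions/site) from
#'     pairwise transition/transversion proportions and empirical base
#'     frequencies; HKY is its equal-purine/pyrimidine-rate special case. The
#'     invariant-sites component of HKY+I is deliberately not applied here:
#'     at the sub-percent divergences this package targets the correction is
#'     negligible and its closed form ill-conditioned.}
#' }
#'
#' @param aln a [dna_alignment].
#' @param model one of `"raw_differences"`, `"p_distance"`, `"TN93"`.
#' @return A symmetric numeric matrix with ids as dimnames and attributes
#'   `model` and `units`.
#' @examples
#' aln <- dna_alignment(c(a = "ACGTACGT", b = "ACGTACGA"))
#' pairwise_distance(aln, "raw_differences")
#' @export
pairwise_distance <- function(aln,
                              model = c("raw_differences", "p_distance", "TN93")) {
  stopifnot(inherits(aln, "dna_alignment"))
  model <- match.arg(model)
  ids <- rownames(aln)
  n <- nrow(aln)

  resolved <- matrix(aln %in% c("A", "C", "G", "T"), nrow = n)
  comparable <- resolved %*% t(resolved)
  if (n >= 2) {
    off <- comparable[upper.tri(comparable)]
    if (any(off == 0)) {
      idx <- which(comparable == 0 & upper.tri(comparable), arr.ind = TRUE)[1, ]
      abort(sprintf("no comparable sites for pair (%s, %s)",
                    ids[idx[1]], ids[idx[2]]))
    }
  }

  if (model %in% c("raw_differences", "p_distance")) {
    matches <- matrix(0, n, n)
    for (b in c("A", "C", "G", "T")) {
      ib <- matrix(aln == b, nrow = n)
      matches <- matches + ib %*% t(ib)
    }
    diffs <- comparable - matches
    d <- if (model == "raw_differences") diffs else diffs / comparable
    units <- if (model == "raw_differences") "sites" else "substitutions/site"
  } else {
    dn <- ape::as.DNAbin(unclass(aln))
    d <- as.matrix(ape::dist.dna(dn, model = "TN93", pairwise.deletion = TRUE))
    if (any(!is.finite(d))) {
      abort(paste0("TN93 distance undefined for at least one pair ",
                   "(log argument <= 0: saturation); use model = \"p_distance\""))
    }
    d <- d[ids, ids, drop = FALSE]
    units <- "substitutions/site"
  }

  dimnames(d) <- list(ids, ids)
  diag(d) <- 0
  structure(d, model = model, units = units)
}

#' Mean pairwise genetic distance between groups of individuals
#'
#' @param d distance matrix from [pairwise_distance()].
#' @param ids_a,ids_b character vectors of sample ids.
#' @return Mean of `d[a, b]` over all cross pairs (within-group when
#'   `ids_a == ids_b`, excluding self pairs).
#' @export
mean_group_distance <- function(d, ids_a, ids_b) {
  sub <- d[ids_a, ids_b, drop = FALSE]
  if (identical(sort(ids_a), sort(ids_b))) {
    if (length(ids_a) < 2) return(0)
    m <- sub[lower.tri(sub)]
    return(mean(m))
  }
  mean(sub)
}
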
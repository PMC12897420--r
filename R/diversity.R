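#' Taxonomic diversity of one community
#'
#' Shannon diversity H (natural log), Pielou evenness E = H / ln(S) and
#' Simpson dominance D = sum(p^2), computed over families with positive
#' counts. E is undefined (NA) for a monoculture, where ln(S) = 0.
#'
#' @param counts Non-negative integer abundances for one sampling event;
#'   at least one must be positive.
#' @return Named numeric vector with elements `H`, `E`, `D`.
#' @examples
#' taxonomic_indices(c(10, 5, 5))
#' @export
taxonomic_indices <- function(counts) {
  if (any(counts < 0)) stop("negative counts")
  total <- sum(counts)
  if (total <= 0) stop("all-zero community")
  p <- counts[counts > 0] / total
  s <- length(p)
  h <- -sum(p * log(p))
  e <- if (s > 1) h / log(s) else NA_real_
  c(H = h, E = e, D = sum(p^2))
}

#' Normalise a fuzzy trait matrix to per-trait probability profiles
#'
#' Within each trait block of the schema, each family's affinity scores are
#' divided by their block sum, so the block becomes a probability profile
#' over that trait's categories. Blocks whose scores are all zero carry no
#' information for that family and are flagged missing (left as zeros).
#'
#' @param tm Numeric matrix, families x categories, scores in \[0, 3\];
#'   columns ordered as in `schema`.
#' @param schema Trait schema data frame (see [default_trait_schema()]).
#' @return A list with `profiles` (families x categories matrix of
#'   normalised scores) and `missing` (families x traits logical matrix,
#'   TRUE where a family's block was all zero).
#' @export
normalize_traits <- function(tm, schema = default_trait_schema()) {
  validate_trait_matrix(tm, schema)
  traits <- unique(as.character(schema$trait))
  prof <- tm
  miss <- matrix(FALSE, nrow(tm), length(traits),
                 dimnames = list(rownames(tm), traits))
  for (tr in traits) {
    cols <- which(as.character(schema$trait) == tr)
    block <- tm[, cols, drop = FALSE]
    sums <- rowSums(block)
    zero <- sums == 0
    sums[zero] <- 1  # leave all-zero blocks as zeros
    prof[, cols] <- block / sums
    miss[, tr] <- zero
  }
  list(profiles = prof, missing = miss)
}

validate_trait_matrix <- function(tm, schema) {
  stopifnot(is.matrix(tm), is.numeric(tm))
  if (ncol(tm) != nrow(schema)) {
    stop("trait matrix has ", ncol(tm), " columns but the schema defines ",
         nrow(schema), " categories")
  }
  if (any(tm < 0) || any(tm > 3)) {
    stop("affinity scores must lie in [0, 3]")
  }
  invisible(tm)
}

#' Pairwise functional distances between families
#'
#' Gower-type distance on fuzzy-coded traits: within each trait, the
#' distance between two families is half the L1 distance between their
#' normalised category profiles (total-variation distance, in \[0, 1\]);
#' the overall distance is the mean over traits that are non-missing for
#' both families.
#'
#' @param prof A list from [normalize_traits()].
#' @param schema Trait schema data frame.
#' @return Symmetric families x families matrix with zero diagonal and
#'   entries in \[0, 1\].
#' @export
trait_distance <- function(prof, schema = default_trait_schema()) {
  profiles <- prof$profiles
  missing <- prof$missing
  n <- nrow(profiles)
  traits <- unique(as.character(schema$trait))
  if (any(rowSums(!missing) == 0)) {
    stop("family with no scored traits: ",
         paste(rownames(profiles)[rowSums(!missing) == 0], collapse = ", "))
  }
  dsum <- matrix(0, n, n)
  nshared <- matrix(0, n, n)
  for (k in seq_along(traits)) {
    cols <- which(as.character(schema$trait) == traits[k])
    block <- profiles[, cols, drop = FALSE]
    dt <- 0.5 * as.matrix(stats::dist(block, method = "manhattan"))
    ok <- outer(!missing[, k], !missing[, k], `&`)
    dsum <- dsum + dt * ok
    nshared <- nshared + ok
  }
  if (any(nshared == 0 & upper.tri(nshared))) {
    stop("family pair sharing no scored trait")
  }
  d <- dsum / nshared
  diag(d) <- 0
  dimnames(d) <- list(rownames(profiles), rownames(profiles))
  d
}

#' Rao's quadratic entropy
#'
#' Abundance-weighted expected functional distance between two randomly
#' drawn individuals: `sum_ij d[i, j] p_i p_j`.
#'
#' @param p Relative abundances (summing to 1 over the listed families;
#'   zero entries are allowed and contribute nothing).
#' @param d Functional distance matrix over the same families.
#' @return Non-negative scalar, at most `max(d)`.
#' @export
rao_entropy <- function(p, d) {
  stopifnot(length(p) == nrow(d), nrow(d) == ncol(d))
  as.numeric(t(p) %*% d %*% p)
}

#' Functional attribute diversity (FAD1)
#'
#' Sum of pairwise functional distances among the families present
#' (positive abundance); abundance-blind beyond presence.
#'
#' @param present Logical (or 0/1) vector marking present families.
#' @param d Functional distance matrix.
#' @return Non-negative scalar; 0 for a single present family.
#' @export
fad1 <- function(present, d) {
  stopifnot(length(present) == nrow(d))
  idx <- which(as.logical(present))
  if (length(idx) < 2) return(0)
  sub <- d[idx, idx, drop = FALSE]
  sum(sub[upper.tri(sub)])
}

#' Community-weighted functional divergence (wFDc)
#'
#' Abundance-weighted mean Euclidean distance of families from the
#' community's abundance-weighted centroid in concatenated trait-profile
#' space. Traits missing for any present family are dropped from the
#' coordinate space for that community so all present families live in the
#' same space.
#'
#' @param p Relative abundances (summing to 1).
#' @param prof A list from [normalize_traits()] covering the same families,
#'   in the same order.
#' @param schema Trait schema data frame.
#' @return Non-negative scalar; 0 when a single family dominates entirely
#'   or all present profiles coincide.
#' @export
wfdc <- function(p, prof, schema = default_trait_schema()) {
  stopifnot(length(p) == nrow(prof$profiles))
  idx <- which(p > 0)
  if (length(idx) < 2) return(0)
  traits <- unique(as.character(schema$trait))
  usable <- traits[colSums(prof$missing[idx, , drop = FALSE]) == 0]
  if (length(usable) == 0) stop("no trait scored for every present family")
  cols <- which(as.character(schema$trait) %in% usable)
  x <- prof$profiles[idx, cols, drop = FALSE]
  w <- p[idx] / sum(p[idx])
  centroid <- colSums(x * w)
  dev <- sqrt(rowSums(sweep(x, 2, centroid)^2))
  sum(w * dev)
}

#' Per-event diversity profile
#'
#' Computes the six diversity indices (H, E, D, Rao, FAD1, wFDc) for every
#' sampling event of an abundance table.
#'
#' @param abundance Counts matrix, families x events (non-negative
#'   integers, at least one positive count per event).
#' @param tm Fuzzy trait matrix for the same families (rows aligned with
#'   `abundance`), scores in \[0, 3\].
#' @param schema Trait schema data frame.
#' @return Data frame with one row per event: `event`, `H`, `E`, `D`,
#'   `Rao`, `FAD1`, `wFDc`.
#' @examples
#' set.seed(1)
#' tm <- gen_trait_matrix(5, seed = 1)
#' ab <- matrix(rpois(5 * 4, 8), 5, 4,
#'              dimnames = list(rownames(tm), paste0("e", 1:4)))
#' diversity_table(ab, tm)
#' @export
diversity_table <- function(abundance, tm, schema = default_trait_schema()) {
  stopifnot(is.matrix(abundance), nrow(abundance) == nrow(tm))
  if (any(abundance < 0)) stop("negative abundances")
  if (any(colSums(abundance) <= 0)) {
    stop("event(s) with no individuals: ",
         paste(colnames(abundance)[colSums(abundance) <= 0], collapse = ", "))
  }
  prof <- normalize_traits(tm, schema)
  d <- trait_distance(prof, schema)
  events <- colnames(abundance)
  if (is.null(events)) events <- as.character(seq_len(ncol(abundance)))
  out <- lapply(seq_len(ncol(abundance)), function(j) {
    counts <- abundance[, j]
    tax <- taxonomic_indices(counts)
    p <- counts / sum(counts)
    data.frame(event = events[j],
               H = tax[["H"]], E = tax[["E"]], D = tax[["D"]],
               Rao = rao_entropy(p, d),
               FAD1 = fad1(counts > 0, d),
               wFDc = wfdc(p, prof, schema))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
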
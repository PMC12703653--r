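# Benchmark-style evaluation of assembled ternary models against a reference
# complex: sequence-alignment-based common-Calpha mapping and pp_RMSD, the
# Calpha RMSD of the protein pair after superposing on the E3 chains only.

#' Map common Calpha residues between a model and a reference
#'
#' Per chain role (E3, POI), the one-letter sequences of the model and
#' reference are globally aligned (match +1, mismatch -1, linear gap -2);
#' aligned non-gap positions with a Calpha present on both sides form the
#' map. Identity below 30 percent triggers a warning (homolog mapping);
#' fewer than 3 mapped residues per role is an error.
#'
#' @param model a \code{ternary_model} (components \code{poi}, \code{e3}).
#' @param reference a \code{ternary_model} or a list with
#'   \code{protein_complex} components \code{poi} and \code{e3}.
#' @return a \code{calpha_map}: per role, a data.frame of paired residue
#'   keys \code{model_chain}, \code{model_resno}, \code{ref_chain},
#'   \code{ref_resno}.
#' @export
common_calpha_map <- function(model, reference) {
  roles <- c("e3", "poi")
  maps <- lapply(roles, function(role) {
    .align_role(model[[role]], reference[[role]], role)
  })
  names(maps) <- roles
  structure(maps, class = "calpha_map")
}

.role_sequence <- function(px) {
  # concatenated over chains in order; keys track (chain, resno)
  chains <- chain_ids(px)
  seq1 <- character(); key_chain <- character(); key_resno <- integer()
  for (ch in chains) {
    s <- chain_sequence(px, ch)
    seq1 <- c(seq1, unname(s))
    key_chain <- c(key_chain, rep(ch, length(s)))
    key_resno <- c(key_resno, as.integer(names(s)))
  }
  list(seq = paste(seq1, collapse = ""), chain = key_chain, resno = key_resno)
}

.align_role <- function(model_px, ref_px, role) {
  ms <- .role_sequence(model_px)
  rs <- .role_sequence(ref_px)
  alphabet <- unique(strsplit(paste0(ms$seq, rs$seq, "X"), "")[[1]])
  mat <- matrix(-1, length(alphabet), length(alphabet),
                dimnames = list(alphabet, alphabet))
  diag(mat) <- 1
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(ms$seq), Biostrings::AAString(rs$seq),
    substitutionMatrix = mat, gapOpening = 0, gapExtension = 2,
    type = "global")
  ap <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  as_ <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  i <- 0L; j <- 0L
  pairs <- matrix(integer(), 0, 2)
  n_match <- 0L; n_col <- 0L
  for (k in seq_along(ap)) {
    if (ap[k] != "-") i <- i + 1L
    if (as_[k] != "-") j <- j + 1L
    if (ap[k] != "-" && as_[k] != "-") {
      pairs <- rbind(pairs, c(i, j))
      n_col <- n_col + 1L
      if (ap[k] == as_[k]) n_match <- n_match + 1L
    }
  }
  if (nrow(pairs) < 3L)
    stop("fewer than 3 mapped residues for the ", toupper(role), " role")
  identity <- n_match / n_col
  if (identity < 0.30)
    warning(sprintf("%s alignment identity %.0f%% < 30%%: homolog mapping",
                    toupper(role), 100 * identity))
  out <- data.frame(model_chain = ms$chain[pairs[, 1]],
                    model_resno = ms$resno[pairs[, 1]],
                    ref_chain = rs$chain[pairs[, 2]],
                    ref_resno = rs$resno[pairs[, 2]])
  attr(out, "identity") <- identity
  out
}

.mapped_calpha <- function(px, chain_col, resno_col, map_df) {
  a <- px$atoms[px$atoms$atom == "CA", ]
  key <- paste(a$chain, a$resno)
  want <- paste(map_df[[chain_col]], map_df[[resno_col]])
  idx <- match(want, key)
  if (anyNA(idx)) stop("mapped residue lacks a Calpha")
  as.matrix(a[idx, c("x", "y", "z")])
}

#' Protein-protein RMSD after E3-only superposition
#'
#' Step 1: Kabsch-superpose the model onto the reference using only the
#' mapped E3 Calpha pairs. Step 2: with that single transform applied to the
#' whole model, compute the RMSD over ALL mapped Calpha atoms of both
#' proteins (degrader excluded), with no re-fitting. Because the alignment
#' uses the E3 only, the value isolates the deviation of the POI's
#' orientation relative to the reference.
#'
#' @param model,reference as in \code{\link{common_calpha_map}}.
#' @param map a \code{calpha_map}; computed on the fly when omitted.
#' @return pp_RMSD in Angstrom.
#' @export
pp_rmsd <- function(model, reference, map = NULL) {
  if (is.null(map)) map <- common_calpha_map(model, reference)
  m_e3 <- .mapped_calpha(model$e3, "model_chain", "model_resno", map$e3)
  r_e3 <- .mapped_calpha(reference$e3, "ref_chain", "ref_resno", map$e3)
  m_poi <- .mapped_calpha(model$poi, "model_chain", "model_resno", map$poi)
  r_poi <- .mapped_calpha(reference$poi, "ref_chain", "ref_resno", map$poi)
  sup <- kabsch_superpose(m_e3, r_e3)
  m_all <- transform_coords(rbind(m_e3, m_poi), sup$transform)
  r_all <- rbind(r_e3, r_poi)
  sqrt(mean(rowSums((m_all - r_all)^2)))
}

#' Rank window-passing models by lig_RMSD and report pp_RMSD
#'
#' Applies the plausibility window, takes up to \code{top_n} models with the
#' lowest lig_RMSD, computes pp_RMSD for each, and reports the table plus a
#' summary (best pp_RMSD, the rank of the model achieving it, and how many
#' fall below \code{threshold}).
#'
#' @param models list of \code{ternary_model} with \code{lig_rmsd} and
#'   normalised scores set.
#' @param reference as in \code{\link{common_calpha_map}}.
#' @param top_n how many models to evaluate (default 100).
#' @param window a \code{\link{plausibility_window}}.
#' @param threshold success cutoff on pp_RMSD in Angstrom (default 10).
#' @return data.frame (rank, lig_rmsd, clash_score, surface_score, pp_rmsd)
#'   with attribute \code{"summary"}; zero rows (with a warning) when no
#'   model passes the window.
#' @export
rank_models_by_ppRMSD <- function(models, reference, top_n = 100L,
                                  window = plausibility_window(),
                                  threshold = 10) {
  passing <- filter_plausible(models, window)
  if (!length(passing)) {
    warning("no model passes the plausibility window")
    out <- data.frame(rank = integer(), lig_rmsd = numeric(),
                      clash_score = numeric(), surface_score = numeric(),
                      pp_rmsd = numeric())
    attr(out, "summary") <- list(best_pp_rmsd = NA_real_,
                                 best_rank = NA_integer_,
                                 n_below_threshold = 0L, n_sampled = 0L)
    return(out)
  }
  lig <- vapply(passing, `[[`, numeric(1), "lig_rmsd")
  ord <- order(lig)
  sel <- passing[ord[seq_len(min(top_n, length(ord)))]]
  map <- common_calpha_map(sel[[1]], reference)
  pp <- vapply(sel, pp_rmsd, numeric(1), reference = reference, map = map)
  out <- data.frame(
    rank = vapply(sel, `[[`, integer(1), "rank"),
    lig_rmsd = vapply(sel, `[[`, numeric(1), "lig_rmsd"),
    clash_score = vapply(sel, `[[`, numeric(1), "clash_score"),
    surface_score = vapply(sel, `[[`, numeric(1), "surface_score"),
    pp_rmsd = pp)
  attr(out, "summary") <- list(
    best_pp_rmsd = min(pp),
    best_rank = out$rank[which.min(pp)],
    n_below_threshold = sum(pp < threshold),
    n_sampled = length(sel))
  out
}
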
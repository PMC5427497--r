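# Protein-level aggregation: each cell's class probabilities are treated
# as a draw from a multinomial over compartments; with a symmetric
# Dirichlet prior the posterior concentration for a protein is the prior
# plus the soft count (sum of per-cell probability vectors).  The MAP
# compartment is the largest concentration, equivalently the largest soft
# count.

#' Dirichlet posterior over compartments for one protein
#'
#' `alpha_k = prior_alpha + sum_cells p_k(cell)` — "softly counting" the
#' cells assigned to each compartment.  An empty cell list returns the
#' prior itself (with a warning) and `n_cells = 0`.
#'
#' @param probs Matrix of per-cell class probabilities (rows = cells,
#'   named columns = compartments), or a single-row vector.
#' @param prior_alpha Positive symmetric prior concentration (1 = flat
#'   uninformative prior).
#' @param protein_id Optional id stored in the result; if `probs` carries
#'   a `protein_id` attribute with several distinct values, mixed input is
#'   rejected.
#' @return A `dirichlet_posterior`: list with `alpha`, `n_cells`,
#'   `prior_alpha`, `protein_id`.
#' @export
dirichlet_posterior <- function(probs, prior_alpha = 1, protein_id = NA) {
  if (!(is.numeric(prior_alpha) && length(prior_alpha) == 1 && prior_alpha > 0))
    stop("prior_alpha must be a positive scalar")
  pid <- attr(probs, "protein_id") %||% protein_id
  if (length(unique(stats::na.omit(pid))) > 1)
    stop("cells from multiple proteins: ",
         paste(unique(pid), collapse = ", "))
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = length(probs) > 0,
                                           dimnames = list(NULL, names(probs)))
  n <- nrow(probs)
  if (n == 0) {
    warning("no cells observed; posterior equals the prior")
    alpha <- stats::setNames(rep(prior_alpha, ncol(probs)), colnames(probs))
  } else {
    bad <- abs(rowSums(probs) - 1) > 1e-6 | apply(probs < 0, 1, any)
    if (any(bad)) stop(sum(bad), " rows are not probability simplices")
    alpha <- prior_alpha + colSums(probs)
  }
  structure(list(alpha = alpha, n_cells = n, prior_alpha = prior_alpha,
                 protein_id = pid[1]),
            class = "dirichlet_posterior")
}

#' MAP compartment call from a posterior
#'
#' Returns the compartment with the largest posterior concentration
#' (equivalently, the largest summed per-cell probability).  Exact ties
#' resolve to the lowest class index and are flagged via the `"tie"`
#' attribute.  A posterior built from zero cells has no data to call and
#' is rejected.
#'
#' @param posterior A [dirichlet_posterior()].
#' @return Compartment name (character scalar) with attribute `tie`.
#' @export
map_compartment <- function(posterior) {
  stopifnot(inherits(posterior, "dirichlet_posterior"))
  if (posterior$n_cells < 1)
    stop("cannot call a compartment from 0 cells")
  k <- which.max(posterior$alpha)   # first maximum = lowest index
  tie <- sum(posterior$alpha == posterior$alpha[k]) > 1
  structure(names(posterior$alpha)[k], tie = tie)
}

#' Top-k compartments with posterior mass fractions
#'
#' Compartments ordered by decreasing concentration; the mass fraction
#' `(alpha_k - prior) / sum(alpha - prior)` estimates the frequency of
#' cells in which the protein resides in compartment k.
#'
#' @param posterior A [dirichlet_posterior()].
#' @param k Number of compartments to report (1..K).
#' @return data.frame with columns `label`, `alpha`, `mass_fraction`.
#' @export
top_k_classes <- function(posterior, k) {
  stopifnot(inherits(posterior, "dirichlet_posterior"))
  K <- length(posterior$alpha)
  if (!(k >= 1 && k <= K)) stop("k must be in 1..", K)
  soft <- posterior$alpha - posterior$prior_alpha
  tot <- sum(soft)
  o <- order(posterior$alpha, decreasing = TRUE)[seq_len(k)]
  data.frame(label = names(posterior$alpha)[o],
             alpha = unname(posterior$alpha[o]),
             mass_fraction = if (tot > 0) unname(soft[o]) / tot else
               rep(NA_real_, k),
             row.names = NULL)
}

#' Aggregate per-cell probabilities into per-protein calls
#'
#' Groups probability rows by protein, computes each protein's Dirichlet
#' posterior and MAP call, and reports the top-k mass fractions.
#'
#' @param probs Matrix of per-cell probabilities (named class columns).
#' @param protein_ids Character vector, one id per row of `probs`.
#' @param prior_alpha Symmetric prior concentration.
#' @param top_k Number of classes to report per protein.
#' @return data.frame, one row per protein: `protein_id`, `n_cells`,
#'   `map_label`, `tie`, `top_labels` (comma-joined), `top_fractions`
#'   (comma-joined), plus a `posteriors` attribute (named list).
#' @export
aggregate_proteins <- function(probs, protein_ids, prior_alpha = 1,
                               top_k = 3) {
  stopifnot(nrow(probs) == length(protein_ids))
  ids <- unique(protein_ids)
  posts <- list()
  rows <- lapply(ids, function(id) {
    pp <- probs[protein_ids == id, , drop = FALSE]
    post <- dirichlet_posterior(pp, prior_alpha, protein_id = id)
    posts[[id]] <<- post
    call <- map_compartment(post)
    tk <- top_k_classes(post, min(top_k, ncol(probs)))
    data.frame(protein_id = id, n_cells = post$n_cells,
               map_label = as.character(call), tie = attr(call, "tie"),
               top_labels = paste(tk$label, collapse = ","),
               top_fractions = paste(sprintf("%.4f", tk$mass_fraction),
                                     collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "posteriors") <- posts
  out
}

#' Drop proteins observed in too few cells
#'
#' @param protein_calls data.frame from [aggregate_proteins()] (needs
#'   `n_cells`).
#' @param min_cells Minimum cells required to keep a protein.
#' @return The kept subset; the number removed is reported via message
#'   and the `"n_removed"` attribute.
#' @export
filter_min_cells <- function(protein_calls, min_cells) {
  stopifnot(min_cells >= 1)
  keep <- protein_calls$n_cells >= min_cells
  if (!any(keep)) warning("no protein has >= ", min_cells, " cells")
  message(sum(!keep), " protein(s) removed by min_cells = ", min_cells)
  out <- protein_calls[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}
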
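#' EM parameter learning for a two-slice DBN
#'
#' Expectation-maximization over partially observed state sequences. Each
#' E-step runs exact forward/backward interface inference per sequence and
#' accumulates expected sufficient statistics for every CPT cell; the M-step
#' renormalizes them (with a small additive pseudocount to avoid
#' zero-probability lock-in). The log-likelihood is non-decreasing across
#' iterations; with fully observed data one step reproduces the empirical
#' conditional frequencies. Nodes whose slice-2 CPT reuses the slice-1 table
#' (no inter-slice parents) are learned as a single tied parameter set,
#' pooling counts from all slices.
#'
#' Unlike [dbn_evidence()], learning data may clamp hidden nodes too: a
#' training record is simply a state matrix with gaps.
#'
#' @param model starting [dbn_model()] (structure is kept; parameters are
#'   re-estimated).
#' @param data list of integer matrices, one per sequence: rows = slices,
#'   columns named by node, entries 1 = false / 2 = true / `NA` = missing.
#' @param max_iters maximum EM iterations.
#' @param tol stop when the log-likelihood improves by less than `tol`.
#' @param pseudocount additive smoothing count per CPT cell.
#' @return list with `model` (fitted), `loglik` (per-iteration trace,
#'   non-decreasing) and `iterations`.
#' @export
em_learn <- function(model, data, max_iters = 100, tol = 1e-6,
                     pseudocount = 1e-6) {
  if (!length(data)) stop("em_learn needs at least one sequence")
  data <- lapply(data, function(m) {
    m <- as.matrix(m)
    miss <- setdiff(model$nodes$name, colnames(m))
    if (length(miss)) stop("sequence missing node column(s): ",
                           paste(miss, collapse = ", "))
    storage.mode(m) <- "integer"
    for (v in model$nodes$name) {
      bad <- !is.na(m[, v]) & (m[, v] < 1L | m[, v] > model$arity[[v]])
      if (any(bad)) stop("states for '", v, "' outside 1..",
                         model$arity[[v]])
    }
    m
  })
  evlists <- lapply(data, function(m) {
    lapply(seq_len(nrow(m)), function(t) {
      s <- m[t, ]
      s <- s[!is.na(s)]
      stats::setNames(as.integer(s), names(s))
    })
  })
  ll_trace <- numeric(0)
  cur <- model
  for (iter in seq_len(max_iters)) {
    zero_counts <- function(cpts) lapply(cpts, function(cpt) {
      array(0, dim = dim(cpt$values))
    })
    c1 <- zero_counts(cur$slice1)
    c2 <- zero_counts(cur$slice2)
    ll <- 0
    cache <- struct_cache()
    for (evlist in evlists) {
      fw <- forward_pass(cur, evlist, cache)
      ll <- ll + fw$loglik
      betas <- backward_pass(fw)
      for (t in seq_along(evlist)) {
        S <- fw$structs[[t]]
        a_prev <- if (t == 1) 1 else fw$alphas[[t - 1]]
        J <- (a_prev * S$Wfull) *
          rep(betas[[t]][S$iface_idx], each = S$Kprev)
        w <- as.vector(J)
        w <- w / sum(w)
        tgt <- if (t == 1) "c1" else "c2"
        acc <- get(tgt)
        for (v in cur$nodes$name) {
          agg <- rowsum(w, group = S$lin_idx[[v]])
          cells <- as.integer(rownames(agg))
          acc[[v]][cells] <- acc[[v]][cells] + agg[, 1]
        }
        assign(tgt, acc)
      }
    }
    ll_trace <- c(ll_trace, ll)
    # M-step: normalize expected counts along the child dimension
    renorm <- function(counts, template) {
      cols <- matrix(counts + pseudocount,
                     ncol = dim(template$values)[length(dim(template$values))])
      probs <- cols / rowSums(cols)
      template$values <- array(as.vector(probs), dim = dim(template$values))
      template
    }
    new1 <- cur$slice1
    new2 <- cur$slice2
    for (v in cur$nodes$name) {
      if (v %in% cur$tied) {
        new1[[v]] <- renorm(c1[[v]] + c2[[v]], cur$slice1[[v]])
        new2[[v]] <- new1[[v]]
      } else {
        new1[[v]] <- renorm(c1[[v]], cur$slice1[[v]])
        new2[[v]] <- renorm(c2[[v]], cur$slice2[[v]])
      }
    }
    cur$slice1 <- new1
    cur$slice2 <- new2
    if (iter > 1 &&
        abs(ll_trace[iter] - ll_trace[iter - 1]) < tol) break
  }
  list(model = cur, loglik = ll_trace, iterations = length(ll_trace))
}
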
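#' Per-slice evidence for a dynamic Bayesian network
#'
#' @param states list of named state vectors, one per slice; element `t`
#'   gives the observed nodes of slice `t` (states as logical, `"true"` /
#'   `"false"`, or 1 = false / 2 = true). Elements may be `NULL` / empty for
#'   slices with no observations. Alternatively a list named by slice index
#'   (`"3" = c(Sl = 2)`), with `horizon` at least the largest named index.
#' @param horizon number of slices `T` the evidence spans.
#' @return object of class `dbn_evidence`: a list of per-slice named integer
#'   vectors of length `horizon`.
#' @export
dbn_evidence <- function(states = list(), horizon = NULL) {
  nm <- names(states)
  if (!is.null(nm) && any(nm != "") && all(grepl("^[0-9]+$", nm[nm != ""]))) {
    idx <- as.integer(nm)
    horizon <- if (is.null(horizon)) max(idx, 0L) else as.integer(horizon)
    out <- vector("list", horizon)
    for (i in seq_along(states)) out[[idx[i]]] <- states[[i]]
  } else {
    horizon <- if (is.null(horizon)) length(states) else as.integer(horizon)
    if (horizon < length(states)) stop("horizon shorter than evidence")
    out <- vector("list", horizon)
    out[seq_along(states)] <- states
  }
  if (horizon < 1) stop("evidence horizon must be >= 1")
  out <- lapply(out, function(s) {
    if (is.null(s) || length(s) == 0) {
      return(stats::setNames(integer(0), character(0)))
    }
    if (is.null(names(s)) || any(names(s) == "")) {
      stop("evidence states must be named by node")
    }
    v <- vapply(seq_along(s), function(j) state_index(s[[j]]), integer(1))
    stats::setNames(v, names(s))
  })
  structure(out, class = "dbn_evidence", horizon = horizon)
}

#' @export
print.dbn_evidence <- function(x, ...) {
  cat("DBN evidence over", attr(x, "horizon"), "slice(s);",
      sum(lengths(unclass(x))), "observation(s)\n")
  invisible(x)
}

check_evidence <- function(model, ev, allow_hidden = FALSE) {
  obs <- model$nodes$name[model$nodes$role == "observable"]
  for (t in seq_along(ev)) {
    s <- ev[[t]]
    unknown <- setdiff(names(s), model$nodes$name)
    if (length(unknown)) stop("evidence names unknown node(s): ",
                              paste(unknown, collapse = ", "))
    if (!allow_hidden) {
      bad <- setdiff(names(s), obs)
      if (length(bad)) stop("evidence on hidden node(s): ",
                            paste(bad, collapse = ", "))
    }
    for (v in names(s)) {
      if (s[[v]] < 1 || s[[v]] > model$arity[[v]]) {
        stop("evidence state for '", v, "' out of range")
      }
    }
  }
  invisible(ev)
}

# ---------------------------------------------------------------------------
# Interface-based exact inference.
#
# The interface I is the set of nodes with an outgoing inter-slice edge; all
# information flowing from slice t to slice t+1 passes through I_t. Forward
# messages alpha_t(I_t) and backward messages beta_t(I_t) are therefore
# sufficient statistics, and each slice update only requires summing over
# the slice's (few) unobserved nodes — the classic scheme of operating on
# pairs of neighboring slices at a time.
# ---------------------------------------------------------------------------

iface_nodes <- function(model) {
  model$nodes$name[model$nodes$name %in% model$inter_edges$from]
}

# enumerate slice assignments (observed clamped) in lexicographic order over
# the model's node order with state 1 < 2 and the FIRST node most significant
slice_grid <- function(model, ev) {
  nm <- model$nodes$name
  U <- setdiff(nm, names(ev))
  A <- matrix(1L, nrow = 1, ncol = length(nm), dimnames = list(NULL, nm))
  if (length(U)) {
    levs <- lapply(rev(U), function(v) seq_len(model$arity[[v]]))
    g <- as.matrix(expand.grid(levs, KEEP.OUT.ATTRS = FALSE))
    g <- g[, rev(seq_along(U)), drop = FALSE]
    A <- matrix(1L, nrow = nrow(g), ncol = length(nm),
                dimnames = list(NULL, nm))
    A[, U] <- g
  }
  for (v in names(ev)) A[, v] <- ev[[v]]
  A
}

lin_index <- function(idx, dims) {
  # column-major linear index of a matrix of subscripts
  out <- idx[, 1]
  if (length(dims) > 1) {
    mult <- cumprod(dims)[-length(dims)]
    for (j in 2:length(dims)) out <- out + (idx[, j] - 1L) * mult[j - 1L]
  }
  as.integer(out)
}

# Precompute everything slice-level inference needs for one evidence pattern:
# the assignment grid, the (K_prev x nrows) full factor product Wfull, the
# interface index of every row, the K_prev x K transition matrix M, and per
# node the linear CPT cell index of every (prev-interface, row) combination
# (used by EM to accumulate expected counts).
slice_struct <- function(model, slice, ev) {
  nm <- model$nodes$name
  A <- slice_grid(model, ev)
  nr <- nrow(A)
  iface <- iface_nodes(model)
  ar_if <- vapply(iface, function(v) model$arity[[v]], integer(1))
  K <- if (length(iface)) prod(ar_if) else 1L
  IC <- if (length(iface)) {
    as.matrix(expand.grid(lapply(ar_if, seq_len), KEEP.OUT.ATTRS = FALSE))
  } else matrix(integer(0), nrow = 1, ncol = 0)
  colnames(IC) <- iface
  Kprev <- if (slice == 1) 1L else K
  cpts <- if (slice == 1) model$slice1 else model$slice2
  Wfull <- matrix(1, Kprev, nr)
  lin_idx <- vector("list", length(nm)); names(lin_idx) <- nm
  for (v in nm) {
    cpt <- cpts[[v]]
    d <- dim(cpt$values)
    np <- length(cpt$parents)
    has_prev <- any(cpt$parent_slice == "prev")
    if (!has_prev) {
      idx <- matrix(1L, nr, np + 1L)
      for (j in seq_len(np)) idx[, j] <- A[, cpt$parents[j]]
      idx[, np + 1L] <- A[, v]
      vals <- cpt$values[idx]
      Wfull <- Wfull * rep(vals, each = Kprev)
      lin_idx[[v]] <- rep(lin_index(idx, d), each = Kprev)
    } else {
      idx <- matrix(1L, Kprev * nr, np + 1L)
      for (j in seq_len(np)) {
        idx[, j] <- if (cpt$parent_slice[j] == "prev") {
          rep(IC[, cpt$parents[j]], times = nr)
        } else {
          rep(A[, cpt$parents[j]], each = Kprev)
        }
      }
      idx[, np + 1L] <- rep(A[, v], each = Kprev)
      vals <- cpt$values[idx]
      Wfull <- Wfull * matrix(vals, Kprev, nr)
      lin_idx[[v]] <- lin_index(idx, d)
    }
  }
  iface_idx <- if (length(iface)) {
    mult <- c(1L, cumprod(ar_if)[-length(ar_if)])
    as.integer(1L + (A[, iface, drop = FALSE] - 1L) %*% mult)
  } else rep(1L, nr)
  M <- matrix(0, Kprev, K)
  agg <- rowsum(t(Wfull), group = iface_idx)
  M[, as.integer(rownames(agg))] <- t(agg)
  list(A = A, Wfull = Wfull, iface_idx = iface_idx, M = M,
       lin_idx = lin_idx, nr = nr, Kprev = Kprev, K = K)
}

struct_cache <- function() new.env(parent = emptyenv())

get_struct <- function(model, slice, ev, cache = NULL) {
  if (is.null(cache)) return(slice_struct(model, slice, ev))
  key <- paste(slice, paste(sort(names(ev)), ev[sort(names(ev))],
                            sep = "=", collapse = ","), sep = "|")
  s <- cache[[key]]
  if (is.null(s)) {
    s <- slice_struct(model, slice, ev)
    cache[[key]] <- s
  }
  s
}

# Forward pass over one evidence sequence; returns normalized messages and
# the data log-likelihood.
forward_pass <- function(model, evlist, cache = NULL) {
  T <- length(evlist)
  structs <- vector("list", T)
  alphas <- vector("list", T)
  ll <- 0
  a_prev <- 1
  for (t in seq_len(T)) {
    S <- get_struct(model, if (t == 1) 1 else 2, evlist[[t]], cache)
    structs[[t]] <- S
    a <- if (t == 1) S$M[1, ] else as.vector(crossprod(S$M, a_prev))
    z <- sum(a)
    if (z <= 0) stop("evidence has zero probability under the model (slice ",
                     t, ")")
    alphas[[t]] <- a / z
    ll <- ll + log(z)
    a_prev <- alphas[[t]]
  }
  list(structs = structs, alphas = alphas, loglik = ll)
}

backward_pass <- function(fw) {
  T <- length(fw$structs)
  K <- fw$structs[[T]]$K
  betas <- vector("list", T)
  betas[[T]] <- rep(1, K)
  if (T >= 2) {
    for (t in T:2) {
      b <- as.vector(fw$structs[[t]]$M %*% betas[[t]])
      betas[[t - 1]] <- b / max(b)
    }
  }
  betas
}

# posterior over slice-t assignments (rows of the slice grid), given the
# forward message into the slice and optionally the backward message out
slice_row_weights <- function(fw, t, betas = NULL) {
  S <- fw$structs[[t]]
  a_prev <- if (t == 1) 1 else fw$alphas[[t - 1]]
  u <- as.vector(a_prev %*% S$Wfull)
  if (!is.null(betas)) u <- u * betas[[t]][S$iface_idx]
  u / sum(u)
}

#' Exact posterior trace by interface filtering/smoothing
#'
#' Computes `P(query = true | evidence)` for every slice, exactly. `filter`
#' conditions slice `t` on evidence from slices 1..t; `smooth` on the whole
#' horizon; `predict` filters through the evidence horizon and then
#' propagates the belief forward without further evidence up to `horizon`.
#' Inference uses forward/backward messages over the model's interface (the
#' nodes with outgoing inter-slice edges), i.e. it operates on pairs of
#' neighboring slices at a time and matches [enumerate_posterior()] to
#' numerical precision.
#'
#' @param model a [dbn_model()].
#' @param evidence a [dbn_evidence()] (or a list accepted by it).
#' @param query node name to track (default `"FA"`).
#' @param mode `"filter"`, `"smooth"` or `"predict"`.
#' @param horizon trace length; defaults to the evidence horizon. Must
#'   exceed it for `"predict"` to add predictive slices.
#' @return a `posterior_trace`: data frame with columns `t`, `p`.
#' @export
infer_posterior <- function(model, evidence, query = "FA",
                            mode = c("filter", "smooth", "predict"),
                            horizon = NULL) {
  mode <- match.arg(mode)
  if (!inherits(evidence, "dbn_evidence")) evidence <- dbn_evidence(evidence)
  if (!query %in% model$nodes$name) stop("unknown query node: ", query)
  check_evidence(model, evidence)
  T_ev <- attr(evidence, "horizon")
  T <- if (is.null(horizon)) T_ev else as.integer(horizon)
  if (T < T_ev) stop("horizon shorter than the evidence")
  evlist <- c(unclass(evidence),
              rep(list(stats::setNames(integer(0), character(0))),
                  T - T_ev))
  cache <- struct_cache()
  fw <- forward_pass(model, evlist, cache)
  betas <- if (mode == "smooth") backward_pass(fw) else NULL
  p <- vapply(seq_len(T), function(t) {
    u <- slice_row_weights(fw, t, betas)
    sum(u[fw$structs[[t]]$A[, query] == 2L])
  }, numeric(1))
  structure(data.frame(t = seq_len(T), p = p),
            class = c("posterior_trace", "data.frame"),
            query = query, mode = mode, loglik = fw$loglik)
}

#' @export
print.posterior_trace <- function(x, ...) {
  cat(sprintf("Posterior trace of P(%s = true | evidence), mode '%s', %d slice(s)\n",
              attr(x, "query"), attr(x, "mode"), nrow(x)))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Joint probability of a complete trajectory
#'
#' The chain-rule product of the slice-1 CPT entries at `t = 1` and the
#' slice-2 CPT entries at every later slice, for a fully specified
#' assignment. This is the elementary quantity from which all inference
#' queries follow by marginalization; it is kept as a direct, unoptimized
#' product for oracle use.
#'
#' @param model a [dbn_model()].
#' @param assignment matrix or data frame, one row per slice, one column per
#'   node (named), states 1 = false / 2 = true (or logical).
#' @return scalar probability.
#' @export
joint_probability <- function(model, assignment) {
  A <- as.matrix(assignment)
  if (is.logical(A)) A <- A + 1L
  miss <- setdiff(model$nodes$name, colnames(A))
  if (length(miss)) stop("assignment missing node(s): ",
                         paste(miss, collapse = ", "))
  p <- 1
  for (t in seq_len(nrow(A))) {
    cpts <- if (t == 1) model$slice1 else model$slice2
    for (v in model$nodes$name) {
      cpt <- cpts[[v]]
      idx <- integer(length(cpt$parents) + 1L)
      for (j in seq_along(cpt$parents)) {
        row <- if (cpt$parent_slice[j] == "prev") t - 1L else t
        idx[j] <- A[row, cpt$parents[j]]
      }
      idx[length(idx)] <- A[t, v]
      p <- p * cpt$values[matrix(idx, nrow = 1)]
    }
  }
  p
}

# all completions of the evidence over slices 1..T, with their joint
# probabilities (vectorized); used by the enumeration oracle
enumerate_joint <- function(model, evlist) {
  T <- length(evlist)
  nm <- model$nodes$name
  n <- length(nm)
  cols <- paste(rep(seq_len(T), each = n), rep(nm, T), sep = ".")
  fixed <- rep(NA_integer_, n * T)
  names(fixed) <- cols
  for (t in seq_len(T)) {
    s <- evlist[[t]]
    for (v in names(s)) fixed[paste(t, v, sep = ".")] <- s[[v]]
  }
  free <- which(is.na(fixed))
  if (length(free)) {
    levs <- lapply(free, function(j) {
      seq_len(model$arity[[nm[(j - 1L) %% n + 1L]]])
    })
    g <- as.matrix(expand.grid(levs, KEEP.OUT.ATTRS = FALSE))
    A <- matrix(rep(fixed, each = nrow(g)), nrow = nrow(g),
                dimnames = list(NULL, cols))
    A[, free] <- g
  } else {
    A <- matrix(fixed, nrow = 1, dimnames = list(NULL, cols))
  }
  p <- rep(1, nrow(A))
  for (t in seq_len(T)) {
    cpts <- if (t == 1) model$slice1 else model$slice2
    for (v in nm) {
      cpt <- cpts[[v]]
      np <- length(cpt$parents)
      idx <- matrix(1L, nrow(A), np + 1L)
      for (j in seq_len(np)) {
        tt <- if (cpt$parent_slice[j] == "prev") t - 1L else t
        idx[, j] <- A[, paste(tt, cpt$parents[j], sep = ".")]
      }
      idx[, np + 1L] <- A[, paste(t, v, sep = ".")]
      p <- p * cpt$values[idx]
    }
  }
  list(A = A, p = p)
}

#' Brute-force posterior by enumeration
#'
#' Marginalizes the complete joint distribution directly: sums the joint
#' probability of every completion of the evidence, with and without the
#' query condition. Exponential in the number of variables — guarded at
#' `n_nodes * T <= 24` binary-equivalent variables — and intended as the
#' independent oracle against which the interface algorithm is checked.
#'
#' @param model a [dbn_model()].
#' @param evidence a [dbn_evidence()] (or list accepted by it).
#' @param query node name.
#' @param t0 slice at which the query node is evaluated.
#' @param state queried state (default 2 = true).
#' @return `P(query = state at t0 | evidence)`.
#' @export
enumerate_posterior <- function(model, evidence, query, t0, state = 2L) {
  if (!inherits(evidence, "dbn_evidence")) evidence <- dbn_evidence(evidence)
  check_evidence(model, evidence)
  T <- attr(evidence, "horizon")
  n <- nrow(model$nodes)
  if (n * T > 24) {
    stop("horizon too large for enumeration (", n * T,
         " variables); use infer_posterior()")
  }
  if (!query %in% model$nodes$name) stop("unknown query node: ", query)
  if (t0 < 1 || t0 > T) stop("t0 outside 1..T")
  ej <- enumerate_joint(model, unclass(evidence))
  z <- sum(ej$p)
  if (z <= 0) stop("evidence has zero probability under the model")
  sum(ej$p[ej$A[, paste(t0, query, sep = ".")] == state]) / z
}

#' Most probable explanation (Viterbi / MAP sequence)
#'
#' The jointly most probable assignment of all unobserved nodes over the
#' horizon, given the evidence, computed by max-product dynamic programming
#' over the interface. Exact ties are broken towards the lexicographically
#' smallest sequence (slices in order, nodes in model order, false < true).
#'
#' @param model a [dbn_model()].
#' @param evidence a [dbn_evidence()] (or list accepted by it).
#' @param horizon trace length (default: evidence horizon).
#' @return list with `states` (matrix, slices x nodes, observed clamped) and
#'   `log_prob` (log joint probability of the returned trajectory with the
#'   evidence).
#' @export
viterbi_map <- function(model, evidence, horizon = NULL) {
  if (!inherits(evidence, "dbn_evidence")) evidence <- dbn_evidence(evidence)
  check_evidence(model, evidence)
  T_ev <- attr(evidence, "horizon")
  T <- if (is.null(horizon)) T_ev else as.integer(horizon)
  if (T < T_ev) stop("horizon shorter than the evidence")
  evlist <- c(unclass(evidence),
              rep(list(stats::setNames(integer(0), character(0))),
                  T - T_ev))
  cache <- struct_cache()
  structs <- lapply(seq_len(T), function(t) {
    get_struct(model, if (t == 1) 1 else 2, evlist[[t]], cache)
  })
  K <- structs[[T]]$K
  # backward max-messages V_t(k) = best probability of slices t..T given
  # interface state k entering slice t; normalized per step for stability
  V <- vector("list", T + 1L)
  V[[T + 1L]] <- rep(1, K)
  if (T >= 2) {
    for (t in T:2) {
      S <- structs[[t]]
      sc <- S$Wfull * rep(V[[t + 1L]][S$iface_idx], each = S$Kprev)
      v <- apply(sc, 1, max)
      if (max(v) <= 0) stop("evidence has zero probability under the model")
      V[[t]] <- v / max(v)
    }
  }
  tol <- 1e-12
  nm <- model$nodes$name
  out <- matrix(NA_integer_, T, length(nm), dimnames = list(NULL, nm))
  logp <- 0
  k <- NULL
  for (t in seq_len(T)) {
    S <- structs[[t]]
    sc <- if (t == 1) {
      S$Wfull[1, ] * V[[2L]][S$iface_idx]
    } else {
      S$Wfull[k, ] * V[[t + 1L]][S$iface_idx]
    }
    if (T == 1) sc <- S$Wfull[1, ]
    mx <- max(sc)
    if (mx <= 0) stop("evidence has zero probability under the model")
    r <- which(sc >= mx * (1 - tol))[1]  # rows are in lexicographic order
    out[t, ] <- S$A[r, ]
    logp <- logp + log(if (t == 1) S$Wfull[1, r] else S$Wfull[k, r])
    k <- S$iface_idx[r]
  }
  list(states = out, log_prob = logp)
}
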
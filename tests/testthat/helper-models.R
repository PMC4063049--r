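# Model builders and generators shared across tests. All randomness uses the
# caller's RNG state so tests control seeds explicitly.

# minimal one-hidden-node model: FA prior + a single observable Sl with the
# published sleep likelihoods
tiny_fa_model <- function(prior_true = 0.2) {
  dbn_model(
    nodes = data.frame(name = c("FA", "Sl"),
                       role = c("hidden", "observable")),
    intra_edges = data.frame(from = "FA", to = "Sl"),
    inter_edges = data.frame(from = "FA", to = "FA"),
    slice1 = list(FA = dbn_cpt("FA", c(1 - prior_true, prior_true)),
                  Sl = dbn_cpt("Sl", c(0.4, 0.9, 0.6, 0.1), "FA")),
    slice2 = list(FA = dbn_cpt("FA", c(0.9, 0.95, 0.1, 0.05), "FA", "prev")))
}

rand_dist <- function(n) {
  p <- stats::runif(n) + 0.05  # bounded away from 0 for stable inference
  p / sum(p)
}

rand_cpt <- function(child, parents = character(0),
                     parent_slice = rep("same", length(parents))) {
  ncfg <- 2L^length(parents)
  vals <- t(vapply(seq_len(ncfg), function(i) rand_dist(2L), numeric(2)))
  dbn_cpt(child, as.vector(vals), parents, parent_slice)
}

# a randomized small DBN: hidden chain H plus up to two observables with
# randomly present intra/inter couplings (A -> B within a slice, A => B
# across slices, A => A persistence)
random_small_model <- function() {
  n_obs <- sample(1:2, 1)
  nm <- c("H", c("A", "B")[seq_len(n_obs)])
  intra <- data.frame(from = "H", to = nm[-1])
  ab_intra <- n_obs == 2 && stats::runif(1) < 0.4
  if (ab_intra) intra <- rbind(intra, data.frame(from = "A", to = "B"))
  inter <- data.frame(from = "H", to = "H")
  aa_inter <- n_obs >= 1 && stats::runif(1) < 0.4
  ab_inter <- n_obs == 2 && stats::runif(1) < 0.4
  if (aa_inter) inter <- rbind(inter, data.frame(from = "A", to = "A"))
  if (ab_inter) inter <- rbind(inter, data.frame(from = "A", to = "B"))
  par1 <- function(v) intra$from[intra$to == v]
  slice1 <- stats::setNames(lapply(nm, function(v) rand_cpt(v, par1(v))),
                            nm)
  slice2 <- stats::setNames(lapply(nm, function(v) {
    prev <- inter$from[inter$to == v]
    same <- par1(v)
    rand_cpt(v, c(prev, same),
             c(rep("prev", length(prev)), rep("same", length(same))))
  }), nm)
  dbn_model(data.frame(name = nm,
                       role = c("hidden", rep("observable", n_obs))),
            intra, inter, slice1, slice2)
}

# random evidence over the observables: each node observed per slice with
# probability p_obs
random_evidence <- function(model, T, p_obs = 0.5) {
  obs <- model$nodes$name[model$nodes$role == "observable"]
  dbn_evidence(lapply(seq_len(T), function(t) {
    on <- obs[stats::runif(length(obs)) < p_obs]
    stats::setNames(sample(1:2, length(on), replace = TRUE), on)
  }), horizon = T)
}

# exhaustive-argmax MAP oracle: enumerates every completion in lexicographic
# order (slices major, nodes in model order, false < true) and takes the
# first maximizer of the scalar joint probability
exhaustive_map <- function(model, evidence) {
  T <- attr(evidence, "horizon")
  nm <- model$nodes$name
  n <- length(nm)
  fixed <- matrix(NA_integer_, T, n, dimnames = list(NULL, nm))
  for (t in seq_len(T)) {
    s <- evidence[[t]]
    for (v in names(s)) fixed[t, v] <- s[[v]]
  }
  free <- which(is.na(t(fixed)))  # row-major over (t, node) = lex order
  grids <- rep(list(1:2), length(free))
  g <- as.matrix(expand.grid(rev(grids)))[, rev(seq_along(free)),
                                          drop = FALSE]
  best_p <- -1
  best <- NULL
  for (r in seq_len(max(1, nrow(g)))) {
    A <- t(fixed)
    if (length(free)) A[free] <- g[r, ]
    A <- t(A)
    colnames(A) <- nm
    p <- joint_probability(model, A)
    if (p > best_p * (1 + 1e-12)) { best_p <- p; best <- A }
  }
  list(states = best, prob = best_p)
}

# the EM parameter-recovery reference model: hidden chain F, observable A
# (tied across slices), observable B with a previous-slice parent A
recovery_model <- function(prior = c(0.5, 0.5),
                           trans = c(0.7, 0.3, 0.3, 0.7),
                           acpt = c(0.8, 0.2, 0.2, 0.8),
                           b1 = c(0.75, 0.25, 0.25, 0.75),
                           b2 = c(0.85, 0.7, 0.3, 0.15,
                                  0.15, 0.3, 0.7, 0.85)) {
  nodes <- data.frame(name = c("F", "A", "B"),
                      role = c("hidden", "observable", "observable"))
  dbn_model(nodes,
            intra_edges = data.frame(from = c("F", "F"), to = c("A", "B")),
            inter_edges = data.frame(from = c("F", "A"), to = c("F", "B")),
            slice1 = list(F = dbn_cpt("F", prior),
                          A = dbn_cpt("A", acpt, "F"),
                          B = dbn_cpt("B", b1, "F")),
            slice2 = list(F = dbn_cpt("F", trans, "F", "prev"),
                          B = dbn_cpt("B", b2, c("A", "F"),
                                      c("prev", "same"))))
}

random_recovery_init <- function() {
  rcol <- function(ncfg) {
    p <- stats::runif(ncfg, 0.2, 0.8)
    c(1 - p, p)
  }
  recovery_model(rcol(1), rcol(2), rcol(2), rcol(2), rcol(4))
}

fe_slice_count <- function(evidence) {
  sum(vapply(seq_along(evidence), function(t) {
    isTRUE(evidence[[t]]["FE"] == 2L)
  }, logical(1)))
}
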
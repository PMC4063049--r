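#' Conditional probability table
#'
#' A CPT stores `P(child | parents)` as a multidimensional array whose
#' dimensions follow the node order `parents..., child` — the child is always
#' the last dimension. States are encoded 1 = false, 2 = true for binary
#' nodes (general arities are supported by the same machinery). `values` may
#' be given as a flat vector in column-major order (first dimension varying
#' fastest), which coincides with the row order in which such tables are
#' conventionally printed.
#'
#' @param child child node name.
#' @param values numeric array or flat vector of probabilities.
#' @param parents character vector of parent names, in index order.
#' @param parent_slice character vector, `"same"` or `"prev"` per parent;
#'   `"prev"` marks a parent from the previous time slice.
#' @param arities integer arities for `c(parents, child)` (default all 2).
#' @return object of class `dbn_cpt`.
#' @export
dbn_cpt <- function(child, values, parents = character(0),
                    parent_slice = rep("same", length(parents)),
                    arities = rep(2L, length(parents) + 1L)) {
  stopifnot(length(parent_slice) == length(parents),
            all(parent_slice %in% c("same", "prev")),
            length(arities) == length(parents) + 1L,
            all(arities >= 2))
  dims <- as.integer(arities)
  if (length(values) != prod(dims)) {
    stop("CPT for '", child, "': expected ", prod(dims), " values, got ",
         length(values))
  }
  arr <- array(as.numeric(values), dim = dims)
  structure(list(child = child, parents = parents,
                 parent_slice = parent_slice, values = arr),
            class = "dbn_cpt")
}

# One column of a CPT = the child distribution for one parent assignment.
# Returns a matrix with one row per parent configuration.
cpt_columns <- function(cpt) {
  d <- dim(cpt$values)
  nchild <- d[length(d)]
  matrix(cpt$values, ncol = nchild)
}

parent_config_label <- function(cpt, row) {
  if (length(cpt$parents) == 0) return("(no parents)")
  d <- dim(cpt$values)
  np <- length(cpt$parents)
  states <- integer(np)
  row0 <- row - 1L
  for (j in seq_len(np)) {
    states[j] <- row0 %% d[j] + 1L
    row0 <- row0 %/% d[j]
  }
  tags <- ifelse(cpt$parent_slice == "prev",
                 paste0(cpt$parents, "_prev"), cpt$parents)
  paste(paste0(tags, "=", states), collapse = ", ")
}

#' Validate (and optionally repair) a CPT
#'
#' Every child distribution must sum to 1 within `1e-9`. With
#' `repair = "complement-false"` a non-normalizing *binary* column is fixed
#' by keeping the child = false (state 1) entry as stored and replacing the
#' child = true entry with its complement; a warning names each repaired
#' column. This mirrors how inconsistently printed tables are reconciled:
#' the false-row entries are trusted.
#'
#' @param cpt a [dbn_cpt()].
#' @param repair `"error"` (default) or `"complement-false"`.
#' @param tol normalization tolerance.
#' @return the (possibly repaired) CPT.
#' @export
validate_cpt <- function(cpt, repair = c("error", "complement-false"),
                         tol = 1e-9) {
  repair <- match.arg(repair)
  cols <- cpt_columns(cpt)
  if (any(cols < -tol) || any(cols > 1 + tol)) {
    stop("CPT for '", cpt$child, "' has probabilities outside [0, 1]")
  }
  sums <- rowSums(cols)
  bad <- which(abs(sums - 1) > tol)
  if (length(bad)) {
    labs <- vapply(bad, function(r) parent_config_label(cpt, r), "")
    if (repair == "complement-false" && ncol(cols) == 2) {
      for (r in bad) cols[r, 2] <- 1 - cols[r, 1]
      cpt$values <- array(as.vector(cols), dim = dim(cpt$values))
      warning("CPT for '", cpt$child,
              "' did not normalize; repaired by complementing the ",
              "child=false entry for parent assignment(s): ",
              paste(labs, collapse = "; "), call. = FALSE)
    } else {
      stop("CPT for '", cpt$child, "' does not normalize for parent ",
           "assignment(s): ", paste(labs, collapse = "; "),
           " (column sums ", paste(signif(sums[bad], 6), collapse = ", "),
           ")")
    }
  }
  cpt
}

#' Two-slice dynamic Bayesian network
#'
#' Defines a discrete DBN by its node set, intra-slice and inter-slice edges
#' and the CPTs of the first two slices; the two-slice structure repeats for
#' every later slice. Nodes without inter-slice parents may omit a slice-2
#' CPT, in which case the slice-1 CPT is reused in every slice (and treated
#' as one tied parameter set by EM).
#'
#' @param nodes data frame with columns `name`, `role` (`"hidden"` or
#'   `"observable"`) and optional `arity` (default 2).
#' @param intra_edges,inter_edges two-column matrices/data frames of
#'   `from, to` node names; inter edges run from slice t-1 to slice t.
#' @param slice1,slice2 named lists of [dbn_cpt()] (slice2 may omit nodes
#'   without inter-slice parents).
#' @param repair passed to [validate_cpt()].
#' @return object of class `dbn_model`.
#' @export
dbn_model <- function(nodes, intra_edges, inter_edges, slice1, slice2,
                      repair = "error") {
  if (!all(c("name", "role") %in% names(nodes))) {
    stop("nodes needs columns 'name' and 'role'")
  }
  if (anyDuplicated(nodes$name)) stop("node names must be unique")
  if (!all(nodes$role %in% c("hidden", "observable"))) {
    stop("node role must be 'hidden' or 'observable'")
  }
  if (is.null(nodes$arity)) nodes$arity <- 2L
  nodes$arity <- as.integer(nodes$arity)
  edge_df <- function(e) {
    if (is.null(e) || length(e) == 0 || NROW(e) == 0) {
      return(data.frame(from = character(0), to = character(0)))
    }
    e <- as.data.frame(e, stringsAsFactors = FALSE)
    names(e) <- c("from", "to")
    e$from <- as.character(e$from); e$to <- as.character(e$to)
    e
  }
  intra <- edge_df(intra_edges)
  inter <- edge_df(inter_edges)
  nm <- nodes$name
  for (e in list(intra, inter)) {
    unknown <- setdiff(unique(c(e$from, e$to)), nm)
    if (length(unknown)) stop("edge references unknown node(s): ",
                              paste(unknown, collapse = ", "))
  }
  if (any(intra$from == intra$to)) stop("intra-slice self-loops not allowed")
  topo <- topo_order(nm, intra)  # errors on intra-slice cycles

  arity_of <- stats::setNames(nodes$arity, nm)
  intra_parents <- function(v) intra$from[intra$to == v]
  inter_parents <- function(v) inter$from[inter$to == v]

  slice1 <- lapply(slice1, validate_cpt, repair = repair)
  slice2 <- lapply(slice2, validate_cpt, repair = repair)

  for (v in nm) {
    c1 <- slice1[[v]]
    if (is.null(c1)) stop("missing slice-1 CPT for node '", v, "'")
    if (!setequal(c1$parents, intra_parents(v)) ||
        any(c1$parent_slice != "same")) {
      stop("slice-1 CPT for '", v,
           "' must have exactly the intra-slice parents (",
           paste(intra_parents(v), collapse = ", "), ")")
    }
  }
  tied <- character(0)
  for (v in nm) {
    c2 <- slice2[[v]]
    ip <- inter_parents(v)
    if (is.null(c2)) {
      if (length(ip)) stop("node '", v, "' has inter-slice parents but no ",
                           "slice-2 CPT")
      slice2[[v]] <- slice1[[v]]
      tied <- c(tied, v)
    } else {
      want_prev <- sort(ip)
      got_prev <- sort(c2$parents[c2$parent_slice == "prev"])
      got_same <- sort(c2$parents[c2$parent_slice == "same"])
      if (!identical(want_prev, got_prev) ||
          !identical(sort(intra_parents(v)), got_same)) {
        stop("slice-2 CPT for '", v, "' parents inconsistent with edges")
      }
    }
  }
  structure(list(nodes = nodes, intra_edges = intra, inter_edges = inter,
                 slice1 = slice1, slice2 = slice2, tied = tied,
                 topo = topo, arity = arity_of),
            class = "dbn_model")
}

# Kahn topological sort of the intra-slice DAG; errors on a cycle.
topo_order <- function(nm, intra) {
  indeg <- stats::setNames(integer(length(nm)), nm)
  for (v in intra$to) indeg[v] <- indeg[v] + 1L
  out <- character(0)
  ready <- nm[indeg[nm] == 0L]
  while (length(ready)) {
    v <- ready[1]; ready <- ready[-1]
    out <- c(out, v)
    kids <- intra$to[intra$from == v]
    for (k in kids) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) ready <- c(ready, k)
    }
  }
  if (length(out) != length(nm)) stop("intra-slice graph has a cycle")
  out
}

#' @export
print.dbn_model <- function(x, ...) {
  cat("Two-slice dynamic Bayesian network\n")
  cat("  nodes:", paste0(x$nodes$name,
                         ifelse(x$nodes$role == "hidden", "*", ""),
                         collapse = ", "),
      "(* = hidden)\n")
  cat("  intra edges:", if (nrow(x$intra_edges))
    paste(x$intra_edges$from, "->", x$intra_edges$to, collapse = ", ")
    else "none", "\n")
  cat("  inter edges:", if (nrow(x$inter_edges))
    paste(x$inter_edges$from, "=>", x$inter_edges$to, collapse = ", ")
    else "none", "\n")
  if (length(x$tied)) {
    cat("  slice-1 CPT reused in later slices for:",
        paste(x$tied, collapse = ", "), "\n")
  }
  invisible(x)
}

# Coerce a state given as TRUE/FALSE, "true"/"false", or 1..arity integer.
state_index <- function(x, arity = 2L) {
  if (is.logical(x)) return(as.integer(x) + 1L)
  if (is.character(x)) {
    i <- match(tolower(x), c("false", "true"))
    if (any(is.na(i))) stop("unknown state label: ", paste(x, collapse = ","))
    return(i)
  }
  xi <- as.integer(x)
  if (any(is.na(xi) | xi < 1L | xi > arity)) {
    stop("state out of range 1..", arity)
  }
  xi
}

#' Look up a stored CPT entry
#'
#' Returns `P(child = child_state | parents = parent_assignment)` exactly as
#' stored. Previous-slice parents are keyed by `"<name>_prev"` (a plain name
#' is also accepted when unambiguous). States may be given as logical,
#' `"true"`/`"false"`, or integers 1 (false) / 2 (true).
#'
#' @param model a [dbn_model()].
#' @param slice 1 or 2.
#' @param child child node name.
#' @param parent_assignment named list/vector covering every parent.
#' @param child_state the child state queried.
#' @return the stored probability.
#' @export
cpt_lookup <- function(model, slice, child, parent_assignment = list(),
                       child_state) {
  stopifnot(slice %in% c(1, 2))
  cpt <- (if (slice == 1) model$slice1 else model$slice2)[[child]]
  if (is.null(cpt)) stop("no CPT for node '", child, "'")
  keys <- ifelse(cpt$parent_slice == "prev",
                 paste0(cpt$parents, "_prev"), cpt$parents)
  idx <- integer(length(cpt$parents) + 1L)
  d <- dim(cpt$values)
  for (j in seq_along(cpt$parents)) {
    val <- parent_assignment[[keys[j]]]
    if (is.null(val)) val <- parent_assignment[[cpt$parents[j]]]
    if (is.null(val)) stop("missing parent '", keys[j], "' in assignment")
    idx[j] <- state_index(val, d[j])
  }
  idx[length(idx)] <- state_index(child_state, d[length(d)])
  cpt$values[matrix(idx, nrow = 1)]
}

#' Read a DBN model specification from YAML/JSON
#'
#' The file defines `nodes` (name, role, optional arity), `intra_edges`,
#' `inter_edges` (pairs `[from, to]`), and `cpts` with `slice1`/`slice2`
#' sections. Each CPT gives `parents` (previous-slice parents prefixed
#' `"prev:"`) and `values`, a flat vector in column-major order with the
#' child as the last dimension (states 1 = false, 2 = true) — i.e. exactly
#' the printed row order of a conventional conditional-probability table.
#'
#' @param path file path (YAML or JSON).
#' @param repair passed to [validate_cpt()]; `"complement-false"` repairs
#'   non-normalizing binary columns with a warning.
#' @return a [dbn_model()].
#' @export
read_dbn_model <- function(path, repair = "error") {
  spec <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  dbn_model_from_spec(spec, repair = repair)
}

dbn_model_from_spec <- function(spec, repair = "error") {
  nodes <- do.call(rbind, lapply(spec$nodes, function(n) {
    data.frame(name = n$name, role = n$role,
               arity = if (is.null(n$arity)) 2L else as.integer(n$arity),
               stringsAsFactors = FALSE)
  }))
  arity_of <- stats::setNames(nodes$arity, nodes$name)
  as_edges <- function(e) {
    if (is.null(e) || length(e) == 0) return(NULL)
    do.call(rbind, lapply(e, function(p) {
      data.frame(from = p[[1]], to = p[[2]], stringsAsFactors = FALSE)
    }))
  }
  parse_cpts <- function(section) {
    if (is.null(section)) return(list())
    out <- list()
    for (child in names(section)) {
      entry <- section[[child]]
      raw <- unlist(entry$parents)
      if (is.null(raw)) raw <- character(0)
      prev <- grepl("^prev:", raw)
      pnames <- sub("^prev:", "", raw)
      out[[child]] <- dbn_cpt(
        child, unlist(entry$values), parents = pnames,
        parent_slice = ifelse(prev, "prev", "same"),
        arities = c(unname(arity_of[pnames]), unname(arity_of[child])))
    }
    out
  }
  dbn_model(nodes,
            intra_edges = as_edges(spec$intra_edges),
            inter_edges = as_edges(spec$inter_edges),
            slice1 = parse_cpts(spec$cpts$slice1),
            slice2 = parse_cpts(spec$cpts$slice2),
            repair = repair)
}

#' Write a DBN model specification to YAML
#'
#' Inverse of [read_dbn_model()]: values are emitted flat in column-major
#' order, previous-slice parents prefixed `"prev:"`. Tied slice-2 CPTs
#' (reused slice-1 tables) are not duplicated.
#'
#' @param model a [dbn_model()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dbn_model <- function(model, path) {
  cpt_spec <- function(cpt) {
    raw <- ifelse(cpt$parent_slice == "prev",
                  paste0("prev:", cpt$parents), cpt$parents)
    list(parents = as.list(raw), values = as.numeric(cpt$values))
  }
  spec <- list(
    nodes = lapply(seq_len(nrow(model$nodes)), function(i) {
      list(name = model$nodes$name[i], role = model$nodes$role[i],
           arity = model$nodes$arity[i])
    }),
    intra_edges = lapply(seq_len(nrow(model$intra_edges)), function(i) {
      list(model$intra_edges$from[i], model$intra_edges$to[i])
    }),
    inter_edges = lapply(seq_len(nrow(model$inter_edges)), function(i) {
      list(model$inter_edges$from[i], model$inter_edges$to[i])
    }),
    cpts = list(
      slice1 = lapply(model$slice1, cpt_spec),
      slice2 = lapply(model$slice2[setdiff(model$nodes$name, model$tied)],
                      cpt_spec)))
  yaml::write_yaml(spec, path)
  invisible(path)
}

#' The default 7-node fall-risk model
#'
#' Loads the shipped two-slice network: a hidden fall-risk node `FA` with a
#' prior vector and an `FA -> FA` transition, six observable children of the
#' same-slice `FA` (`Sl` sleeping, `Sh` showering, `C` cooking, `TV`
#' television, `Tr` training, `FE` wearable fall event), and inter-slice
#' dependencies `Sh => Sl`, `Tr => Sh`, `Tr => C` (sleep tends to follow a
#' shower; showers and cooking tend to follow training). The printed
#' conditional tables for `Sl`/`TV` (slice 1) and `Sh`/`C` (slice 2) are
#' included verbatim; the shipped `Sh` slice-2 table does not normalize in
#' two columns and is repaired by complementing the child = false entry,
#' with a warning (suppress with `quiet = TRUE`). All remaining tables are
#' package defaults chosen so that training and cooking carry elevated fall
#' likelihood and consecutive falls are improbable; they can be overridden.
#'
#' @param overrides optional nested list
#'   `list(slice1 = list(node = values), slice2 = ...)` replacing the flat
#'   column-major value vector of the named CPTs.
#' @param quiet suppress the repair warning for the shipped `Sh` table.
#' @return a [dbn_model()].
#' @export
default_model <- function(overrides = NULL, quiet = FALSE) {
  path <- system.file("extdata", "default_model.yaml", package = "fallfusion")
  spec <- yaml::read_yaml(path)
  if (!is.null(overrides)) {
    for (sl in intersect(names(overrides), c("slice1", "slice2"))) {
      for (child in names(overrides[[sl]])) {
        if (is.null(spec$cpts[[sl]][[child]])) {
          stop("override for unknown CPT: ", sl, "/", child)
        }
        spec$cpts[[sl]][[child]]$values <- overrides[[sl]][[child]]
        # overrides must normalize outright; the lenient repair is reserved
        # for the shipped tables
        entry <- spec$cpts[[sl]][[child]]
        raw <- unlist(entry$parents); if (is.null(raw)) raw <- character(0)
        validate_cpt(dbn_cpt(child, unlist(entry$values),
                             parents = sub("^prev:", "", raw),
                             parent_slice = ifelse(grepl("^prev:", raw),
                                                   "prev", "same")),
                     repair = "error")
      }
    }
  }
  build <- function() dbn_model_from_spec(spec, repair = "complement-false")
  if (quiet) suppressWarnings(build()) else build()
}
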
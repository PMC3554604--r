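# Allen interval algebra: inversion, composition, constraint networks and
# path-consistency propagation.
#
# Each base relation is characterized by the order of the four interval
# endpoints.  Composition is computed, once, by point-order satisfiability:
# r3 belongs to compose(r1, r2) iff the conjunction of the endpoint
# constraints of r1 (on A,B), r2 (on B,C) and r3 (on A,C) — plus start<end
# within each interval — admits a total order of the six endpoints.  The
# resulting 169-cell table is cached for the session.

.teo_cache <- new.env(parent = emptyenv())

# Canonical endpoint realizations (sA, eA, sB, eB) of the 13 relations;
# used to read off the pairwise endpoint orderings that define each one.
.relation_endpoints <- list(
  before        = c(1, 2, 3, 4),
  meets         = c(1, 2, 2, 3),
  overlaps      = c(1, 3, 2, 4),
  finished_by   = c(1, 4, 2, 4),
  contains      = c(1, 4, 2, 3),
  starts        = c(1, 2, 1, 3),
  equals        = c(1, 2, 1, 2),
  started_by    = c(1, 3, 1, 2),
  during        = c(2, 3, 1, 4),
  finishes      = c(2, 3, 1, 3),
  overlapped_by = c(2, 4, 1, 3),
  met_by        = c(2, 3, 1, 2),
  after         = c(3, 4, 1, 2)
)

#' Invert an Allen relation
#'
#' `invert_relation(r)` is the relation that holds from B to A whenever `r`
#' holds from A to B; `equals` is its own inverse.
#'
#' @param r A base relation name.
#' @return The inverse base relation.
#' @export
#' @examples
#' invert_relation("before")
#' invert_relation("meets")
invert_relation <- function(r) {
  check_relation(r)
  inv <- c(before = "after", meets = "met_by", overlaps = "overlapped_by",
           finished_by = "finishes", contains = "during", starts = "started_by",
           equals = "equals", started_by = "starts", during = "contains",
           finishes = "finished_by", overlapped_by = "overlaps",
           met_by = "meets", after = "before")
  unname(inv[r])
}

# Pairwise endpoint constraints of a relation, as a 4-vector over
# {-1 (<), 0 (=), 1 (>)} for (sA?sB, sA?eB, eA?sB, eA?eB).
.endpoint_signs <- function(r) {
  p <- .relation_endpoints[[r]]
  c(sign(p[1] - p[3]), sign(p[1] - p[4]), sign(p[2] - p[3]), sign(p[2] - p[4]))
}

# Satisfiability of a conjunction of atomic order constraints over n points.
# constraints: matrix with columns (i, j, op) where op is -1 (i<j) or 0 (i=j).
# Decided by closing < and = under transitivity and congruence.
.points_satisfiable <- function(n, constraints) {
  LT <- matrix(FALSE, n, n)
  EQ <- diag(n) > 0
  for (k in seq_len(nrow(constraints))) {
    i <- constraints[k, 1]; j <- constraints[k, 2]; op <- constraints[k, 3]
    if (op < 0) LT[i, j] <- TRUE else { EQ[i, j] <- TRUE; EQ[j, i] <- TRUE }
  }
  repeat {
    EQ2 <- EQ | ((EQ %*% EQ) > 0)
    LT2 <- LT | ((LT %*% LT) > 0) | ((LT %*% EQ2) > 0) | ((EQ2 %*% LT) > 0)
    if (identical(EQ2, EQ) && identical(LT2, LT)) break
    EQ <- EQ2; LT <- LT2
  }
  if (any(diag(LT))) return(FALSE)
  if (any(LT & t(LT))) return(FALSE)
  if (any(LT & EQ)) return(FALSE)
  TRUE
}

# Constraint rows binding interval X (points px = c(start, end)) to interval
# Y (points py) under relation r.
.relation_constraints <- function(r, px, py) {
  s <- .endpoint_signs(r)
  pairs <- rbind(c(px[1], py[1]), c(px[1], py[2]), c(px[2], py[1]), c(px[2], py[2]))
  out <- matrix(0L, 0L, 3L)
  for (k in 1:4) {
    if (s[k] < 0) out <- rbind(out, c(pairs[k, 1], pairs[k, 2], -1L))
    else if (s[k] > 0) out <- rbind(out, c(pairs[k, 2], pairs[k, 1], -1L))
    else out <- rbind(out, c(pairs[k, 1], pairs[k, 2], 0L))
  }
  out
}

.build_composition_table <- function() {
  rels <- allen_relations()
  within <- rbind(c(1L, 2L, -1L), c(3L, 4L, -1L), c(5L, 6L, -1L))
  pa <- c(1L, 2L); pb <- c(3L, 4L); pc <- c(5L, 6L)
  tab <- vector("list", 13L * 13L)
  dim(tab) <- c(13L, 13L)
  dimnames(tab) <- list(rels, rels)
  for (r1 in rels) {
    c1 <- .relation_constraints(r1, pa, pb)
    for (r2 in rels) {
      c2 <- .relation_constraints(r2, pb, pc)
      out <- character()
      for (r3 in rels) {
        c3 <- .relation_constraints(r3, pa, pc)
        if (.points_satisfiable(6L, rbind(within, c1, c2, c3))) {
          out <- c(out, r3)
        }
      }
      tab[[r1, r2]] <- out
    }
  }
  tab
}

composition_table <- function() {
  if (is.null(.teo_cache$comp_table)) {
    tab <- .build_composition_table()
    rels <- allen_relations()
    # boolean form for fast set composition: [r1, r2, r3]
    bool <- array(FALSE, c(13L, 13L, 13L), dimnames = list(rels, rels, rels))
    for (i in 1:13) for (j in 1:13) bool[i, j, tab[[i, j]]] <- TRUE
    .teo_cache$comp_table <- tab
    .teo_cache$comp_bool <- bool
  }
  .teo_cache$comp_table
}

#' Compose two Allen relations
#'
#' Returns every base relation r3 such that some triple of intervals A, B, C
#' satisfies `A r1 B`, `B r2 C` and `A r3 C` simultaneously.
#'
#' @param r1,r2 Base relation names.
#' @return Character vector of base relations (never empty).
#' @export
#' @examples
#' compose_relations("before", "before")
#' compose_relations("equals", "during")
compose_relations <- function(r1, r2) {
  check_relation(r1); check_relation(r2)
  composition_table()[[r1, r2]]
}

# Composition lifted to relation sets (13-length logical vectors).
.compose_sets <- function(s1, s2) {
  composition_table()  # ensure cache
  bool <- .teo_cache$comp_bool
  out <- logical(13L)
  for (i in which(s1)) {
    bi <- bool[i, , ]
    for (j in which(s2)) out <- out | bi[j, ]
  }
  out
}

.rel_set <- function(relations) {
  s <- logical(13L)
  names(s) <- allen_relations()
  s[relations] <- TRUE
  s
}

.set_names <- function(s) allen_relations()[s]

.invert_set <- function(s) {
  out <- logical(13L)
  names(out) <- allen_relations()
  for (r in .set_names(s)) out[invert_relation(r)] <- TRUE
  out
}

#' Build a qualitative constraint network from a temporal graph
#'
#' Nodes are the graph's events (in sorted-id order, for reproducible
#' propagation traces); each directed edge holds the disjunction of base
#' relations still possible between the pair.  Unconstrained pairs start at
#' the full 13-relation set; each assertion intersects its edge (and the
#' inverse edge) down.
#'
#' @param graph A [temporal_graph()].
#' @return An object of class `constraint_network` with fields `ids` and
#'   `edges` (an n x n x 13 logical array).
#' @export
constraint_network <- function(graph) {
  stopifnot(is_temporal_graph(graph))
  ids <- sort(event_ids(graph))
  n <- length(ids)
  edges <- array(TRUE, c(n, n, 13L), dimnames = list(ids, ids, allen_relations()))
  for (i in seq_len(n)) {
    edges[i, i, ] <- .rel_set("equals")
  }
  for (a in graph$assertions) {
    i <- match(a$source, ids); j <- match(a$target, ids)
    if (i == j) next
    edges[i, j, ] <- edges[i, j, ] & .rel_set(a$relation)
    edges[j, i, ] <- edges[j, i, ] & .rel_set(invert_relation(a$relation))
  }
  structure(list(ids = ids, edges = edges,
                 tightened = matrix(FALSE, n, n, dimnames = list(ids, ids))),
            class = "constraint_network")
}

#' @export
print.constraint_network <- function(x, ...) {
  n <- length(x$ids)
  cat(sprintf("<constraint network> %d nodes\n", n))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    s <- x$edges[i, j, ]
    if (!all(s)) {
      cat(sprintf("  %s -> %s: {%s}\n", x$ids[i], x$ids[j],
                  paste(.set_names(s), collapse = ", ")))
    }
  }
  invisible(x)
}

#' Propagate a constraint network to path consistency
#'
#' Iterates `edge(i, j) <- edge(i, j) ∩ compose(edge(i, k), edge(k, j))`
#' over all triples, to fixpoint.  Every output edge is a subset of the
#' corresponding input edge; tightened edges are marked as inferred.
#'
#' @param net A [constraint_network()].
#' @return The path-consistent network.
#' @export
propagate_constraints <- function(net) {
  stopifnot(inherits(net, "constraint_network"))
  n <- length(net$ids)
  if (n < 2L) return(net)
  edges <- net$edges
  tightened <- net$tightened
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      for (k in seq_len(n)) {
        if (k == i || k == j) next
        comp <- .compose_sets(edges[i, k, ], edges[k, j, ])
        new <- edges[i, j, ] & comp
        if (!any(new)) {
          abort_inconsistency(
            sprintf("temporal constraints between %s, %s and %s are unsatisfiable",
                    net$ids[i], net$ids[k], net$ids[j]),
            triangle = net$ids[c(i, k, j)]
          )
        }
        if (!identical(new, edges[i, j, ])) {
          edges[i, j, ] <- new
          edges[j, i, ] <- .invert_set(new)
          tightened[i, j] <- TRUE
          tightened[j, i] <- TRUE
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  structure(list(ids = net$ids, edges = edges, tightened = tightened),
            class = "constraint_network")
}

# Backtracking search for an atomic scenario refining the network; returns
# a path-consistent atomic network, or NULL when none exists.  Used by
# validate_graph for graphs small enough (<= 12 events) for exact checking.
find_scenario <- function(net) {
  net <- tryCatch(propagate_constraints(net), teo_inconsistency = function(cnd) NULL)
  if (is.null(net)) return(NULL)
  n <- length(net$ids)
  # first undecided edge, in deterministic order
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    opts <- which(net$edges[i, j, ])
    if (length(opts) > 1L) {
      for (r in opts) {
        trial <- net
        trial$edges[i, j, ] <- .rel_set(allen_relations()[r])
        trial$edges[j, i, ] <- .invert_set(trial$edges[i, j, ])
        found <- find_scenario(trial)
        if (!is.null(found)) return(found)
      }
      return(NULL)
    }
  }
  net
}
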
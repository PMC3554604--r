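# Independent oracles used against the package's reasoner.
#
# oracle_relation reads the Allen relation off concrete numeric endpoints;
# oracle_composition_table enumerates integer endpoint assignments on a
# small grid; oracle_realize builds concrete integer endpoints for an
# atomic network (or proves none exist) by ordering the endpoint classes.

oracle_relation <- function(sA, eA, sB, eB) {
  if (eA < sB) return("before")
  if (eA == sB) return("meets")
  if (sA < sB && eA > sB && eA < eB) return("overlaps")
  if (sA < sB && eA == eB) return("finished_by")
  if (sA < sB && eA > eB) return("contains")
  if (sA == sB && eA < eB) return("starts")
  if (sA == sB && eA == eB) return("equals")
  if (sA == sB && eA > eB) return("started_by")
  if (sA > sB && eA < eB) return("during")
  if (sA > sB && eA == eB) return("finishes")
  if (sA > sB && sA < eB && eA > eB) return("overlapped_by")
  if (sA == eB) return("met_by")
  "after"
}

# Brute force: every assignment of the six endpoints to the integer grid
# 1..6 (enough values to realize any qualitative configuration of three
# intervals), accumulated into a composition table.
oracle_composition_table <- function() {
  grid <- expand.grid(sA = 1:6, eA = 1:6, sB = 1:6, eB = 1:6, sC = 1:6, eC = 1:6)
  grid <- grid[grid$sA < grid$eA & grid$sB < grid$eB & grid$sC < grid$eC, ]
  r1 <- mapply(oracle_relation, grid$sA, grid$eA, grid$sB, grid$eB)
  r2 <- mapply(oracle_relation, grid$sB, grid$eB, grid$sC, grid$eC)
  r3 <- mapply(oracle_relation, grid$sA, grid$eA, grid$sC, grid$eC)
  tab <- list()
  keys <- paste(r1, r2)
  for (k in unique(keys)) {
    tab[[k]] <- sort(unique(r3[keys == k]))
  }
  tab
}

# Atomic n-node network as an n x n relation-name matrix (diag "equals").
# Returns integer endpoint columns (start, end) realizing every edge, or
# NULL when the network has no concrete realization.
oracle_realize <- function(rels) {
  n <- nrow(rels)
  np <- 2L * n
  pt <- function(i, which) 2L * (i - 1L) + which   # which: 1 start, 2 end
  lt <- matrix(FALSE, np, np)
  eq <- diag(np) > 0
  add <- function(i, j, op) {
    if (op < 0) lt[i, j] <<- TRUE
    else if (op > 0) lt[j, i] <<- TRUE
    else { eq[i, j] <<- TRUE; eq[j, i] <<- TRUE }
  }
  for (i in seq_len(n)) add(pt(i, 1), pt(i, 2), -1L)
  signs <- function(r) {
    canon <- list(
      before = c(1, 2, 3, 4), meets = c(1, 2, 2, 3), overlaps = c(1, 3, 2, 4),
      finished_by = c(1, 4, 2, 4), contains = c(1, 4, 2, 3), starts = c(1, 2, 1, 3),
      equals = c(1, 2, 1, 2), started_by = c(1, 3, 1, 2), during = c(2, 3, 1, 4),
      finishes = c(2, 3, 1, 3), overlapped_by = c(2, 4, 1, 3),
      met_by = c(2, 3, 1, 2), after = c(3, 4, 1, 2)
    )[[r]]
    c(sign(canon[1] - canon[3]), sign(canon[1] - canon[4]),
      sign(canon[2] - canon[3]), sign(canon[2] - canon[4]))
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    s <- signs(rels[i, j])
    add(pt(i, 1), pt(j, 1), s[1]); add(pt(i, 1), pt(j, 2), s[2])
    add(pt(i, 2), pt(j, 1), s[3]); add(pt(i, 2), pt(j, 2), s[4])
  }
  # merge equality classes
  parent <- seq_len(np)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(np)) for (j in seq_len(np)) {
    if (eq[i, j]) { ri <- find(i); rj <- find(j); if (ri != rj) parent[rj] <- ri }
  }
  cls <- vapply(seq_len(np), find, integer(1))
  classes <- unique(cls)
  m <- length(classes)
  strict <- matrix(FALSE, m, m)
  for (i in seq_len(np)) for (j in seq_len(np)) {
    if (lt[i, j]) {
      a <- match(cls[i], classes); b <- match(cls[j], classes)
      if (a == b) return(NULL)     # x < x
      strict[a, b] <- TRUE
    }
  }
  # Kahn topological order over the strict-order condensation
  rank <- rep(NA_integer_, m)
  remaining <- rep(TRUE, m)
  next_rank <- 1L
  while (any(remaining)) {
    free <- which(remaining & !apply(strict[, , drop = FALSE], 2,
                                     function(col) any(col & remaining)))
    if (!length(free)) return(NULL)  # cycle through strict edges
    rank[free] <- next_rank
    # spread ranks so every class gets a distinct integer
    for (f in free) { rank[f] <- next_rank; next_rank <- next_rank + 1L }
    remaining[free] <- FALSE
  }
  vals <- rank[match(cls, classes)]
  ends <- matrix(vals, ncol = 2L, byrow = TRUE)  # row i: (start_i, end_i)
  # verify the realization edge by edge
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    got <- oracle_relation(ends[i, 1], ends[i, 2], ends[j, 1], ends[j, 2])
    if (got != rels[i, j]) return(NULL)
  }
  ends
}

# Atomic network read off random concrete intervals (always consistent).
random_scenario_network <- function(n = 5L) {
  s <- sample(1:20, n, replace = TRUE)
  e <- s + sample(1:5, n, replace = TRUE)
  rels <- matrix("equals", n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) rels[i, j] <- oracle_relation(s[i], e[i], s[j], e[j])
  }
  rels
}

# Build a temporal graph carrying the atomic network's upper-triangle edges.
graph_from_network <- function(rels) {
  n <- nrow(rels)
  g <- temporal_graph()
  ids <- vapply(seq_len(n), function(i) add_event(g, sprintf("ev %d", i))$id,
                character(1))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j) assert_relation(g, ids[i], rels[i, j], ids[j])
  }
  list(graph = g, ids = ids)
}

# Path-consistency verdict + closure for an atomic network, through the
# package's reasoner.
pc_closure <- function(rels) {
  gi <- graph_from_network(rels)
  net <- constraint_network(gi$graph)
  tryCatch(propagate_constraints(net), teo_inconsistency = function(cnd) NULL)
}

# Random temporal graph for serialization round-trips.
random_graph <- function(n_events = sample(1:6, 1)) {
  g <- temporal_graph()
  lex <- default_lexicon()
  labels <- c("fever", "macular rash", "nausea", "vaccinated w/MMR",
              "headache & dizziness", "BRIEF GENERALIZED SEIZURE",
              'quoted "label"', "arthralgia, severe")
  ids <- character(n_events)
  for (i in seq_len(n_events)) {
    ids[i] <- add_event(g, sample(labels, 1))$id
  }
  for (i in seq_len(n_events)) {
    roll <- runif(1)
    if (roll < 0.4) {
      pd <- partial_date(sample(1990:2010, 1), sample(1:12, 1), sample(1:28, 1))
      attach_time(g, ids[i], time_instant(format(pd, "%m-%d"), pd))
    } else if (roll < 0.55) {
      attach_time(g, ids[i], time_instant("sometime in July", partial_date(2006, 7)))
    } else if (roll < 0.7) {
      attach_time(g, ids[i], time_interval(
        start = time_instant("start", partial_date(2001, 2, 3)),
        duration = duration(sample(1:9, 1), "day")
      ))
    }
  }
  if (n_events >= 2) {
    pairs <- utils::combn(n_events, 2)
    take <- sample(ncol(pairs), min(ncol(pairs), sample(1:4, 1)))
    for (k in take) {
      i <- pairs[1, k]; j <- pairs[2, k]
      rel <- sample(allen_relations(), 1)
      off <- if (rel %in% c("before", "after") && runif(1) < 0.5) {
        duration(sample(1:30, 1), sample(c("day", "week"), 1))
      } else {
        NULL
      }
      assert_relation(g, ids[i], rel, ids[j], offset = off,
                      provenance = sample(c("stated", "inferred"), 1))
    }
  }
  annotate_events(g, lex)
  g
}
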
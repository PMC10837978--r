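# minimal merge map over a toy roster A..E plus river node
toy_map <- function(nodes = c("A", "B", "C", "D", "E")) {
  m <- stats::setNames(c(nodes, "RM1", "RM2"), c(nodes, "RM1", "RM2"))
  m[c("RM1", "RM2")] <- "RIVER"
  roster <- c(nodes, "RIVER")
  attr(m, "roster") <- roster
  attr(m, "river_node") <- "RIVER"
  m
}

toy_net <- function(seq_recv, gaps_h = NULL, map = toy_map()) {
  n <- length(seq_recv)
  if (is.null(gaps_h)) gaps_h <- rep(1, n)
  starts <- cumsum(gaps_h)
  ev <- do.call(rbind, lapply(seq_len(n), function(i)
    evt("F1", seq_recv[i], starts[i], starts[i] + 0.1)))
  build_network(ev, map)
}

test_that("network construction counts undirected movements and self-edges", {
  # A,B,A -> edge {A,B} multiplicity 2
  net <- toy_net(c("A", "B", "A"))
  expect_equal(net$edges$count[net$edges$a == "A" & net$edges$b == "B"], 2L)

  # consecutive events at the same node: self-edge only beyond the threshold
  net <- toy_net(c("A", "A"), gaps_h = c(1, 30))
  expect_equal(nrow(net$edges), 1)
  expect_true(net$edges$a == "A" && net$edges$b == "A")
  expect_equal(net$edges$count, 1L)
  net <- toy_net(c("A", "A"), gaps_h = c(1, 3))
  expect_equal(nrow(net$edges), 0)

  # back-to-back events at the two receivers of a merged node -> no edge
  map <- toy_map()
  ev <- rbind(evt("F1", "RM1", 0, 1), evt("F1", "RM2", 2, 3))
  net <- build_network(ev, map)
  expect_equal(nrow(net$edges), 0)
  expect_equal(net$nodes, "RIVER")

  expect_error(build_network(evt("F1", "ZZ", 0, 1), map), "unmapped")
})

test_that("node and edge densities match the study combinatorics", {
  a <- fixture_area()
  mm <- node_merge_map(a)
  expect_equal(length(attr(mm, "roster")), 23)

  # an 8-node, 8-edge network out of 23 nodes / 253 possible edges
  net <- toy_net(c("A", "B", "C", "D", "E", "A", "C", "E", "B"),
                 map = toy_map(LETTERS[1:22]))
  expect_equal(length(net$roster), 23)
  expect_equal(length(net$nodes), 5)

  net8 <- list(roster = attr(toy_map(LETTERS[1:22]), "roster"),
               nodes = LETTERS[1:8],
               edges = data.frame(a = LETTERS[1:8],
                                  b = LETTERS[c(2:8, 1)], count = 1L))
  class(net8) <- "fish_network"
  expect_equal(round(node_density(net8), 2), 0.35)
  expect_equal(round(edge_density(net8), 2), 0.03)
  expect_equal(edge_density(net8) * 253, 8)

  # empty network -> both zero
  net0 <- list(roster = net8$roster, nodes = character(0),
               edges = data.frame(a = character(0), b = character(0),
                                  count = integer(0)))
  class(net0) <- "fish_network"
  expect_equal(node_density(net0), 0)
  expect_equal(edge_density(net0), 0)
})

test_that("diameter equals all-pairs brute force on random weighted graphs", {
  floyd <- function(W) {  # independent all-pairs shortest paths
    n <- nrow(W)
    D <- W; D[D == 0] <- Inf; diag(D) <- 0
    for (k in 1:n) for (i in 1:n) for (j in 1:n)
      if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
    D
  }
  set.seed(21)
  for (rep in 1:12) {
    n <- sample(2:10, 1)
    nodes <- paste0("N", seq_len(n))
    full <- t(combn(nodes, 2))
    keep <- runif(nrow(full)) < 0.5
    if (!any(keep)) keep[1] <- TRUE
    edges <- data.frame(a = full[keep, 1], b = full[keep, 2], count = 1L)
    wts <- matrix(0, n, n, dimnames = list(nodes, nodes))
    w <- runif(nrow(edges), 1000, 9000)
    wts[cbind(edges$a, edges$b)] <- w
    wts[cbind(edges$b, edges$a)] <- w
    net <- structure(list(roster = nodes, nodes = nodes, edges = edges),
                     class = "fish_network")
    # oracle: adjacency-weight matrix, Floyd-Warshall, max finite entry
    D <- floyd(wts)
    expect_equal(network_diameter(net, wts),
                 max(D[is.finite(D)]) / 1000)
  }

  # single node -> 0
  net1 <- structure(list(roster = "A", nodes = "A",
                         edges = data.frame(a = character(0), b = character(0),
                                            count = integer(0))),
                    class = "fish_network")
  expect_equal(network_diameter(net1, matrix(0, 1, 1,
                                             dimnames = list("A", "A"))), 0)

  # two nodes, one edge of 5 km
  wts <- matrix(c(0, 5000, 5000, 0), 2, 2, dimnames = list(c("A", "B"),
                                                           c("A", "B")))
  net2 <- structure(list(roster = c("A", "B"), nodes = c("A", "B"),
                         edges = data.frame(a = "A", b = "B", count = 1L)),
                    class = "fish_network")
  expect_equal(network_diameter(net2, wts), 5)
})

test_that("clustering coefficient equals direct triangle/triple enumeration", {
  # triangle -> 1, 4-node star -> 0
  tri <- toy_net(c("A", "B", "C", "A"))
  expect_equal(clustering_coefficient(tri), 1)
  star <- toy_net(c("B", "A", "C", "A", "D"))
  expect_equal(clustering_coefficient(star), 0)
  # no connected triple -> 0 by convention
  expect_equal(clustering_coefficient(toy_net(c("A", "B"))), 0)

  enum_transitivity <- function(adj) {
    n <- nrow(adj); tri <- 0; triple <- 0
    for (i in 1:n) for (j in 1:n) for (k in 1:n) {
      if (i == j || j == k || i == k) next
      if (adj[i, j] && adj[j, k]) {
        triple <- triple + 1
        if (adj[i, k]) tri <- tri + 1
      }
    }
    if (triple == 0) 0 else tri / triple  # (3*triangles)/triples, both x6
  }
  set.seed(33)
  for (rep in 1:8) {
    nodes <- paste0("N", 1:8)
    adj <- matrix(FALSE, 8, 8, dimnames = list(nodes, nodes))
    full <- t(combn(nodes, 2))
    keep <- runif(nrow(full)) < 0.4
    adj[full[keep, , drop = FALSE]] <- TRUE
    adj <- adj | t(adj)
    edges <- data.frame(a = full[keep, 1], b = full[keep, 2], count = 1L)
    net <- structure(list(roster = nodes, nodes = nodes, edges = edges),
                     class = "fish_network")
    expect_equal(clustering_coefficient(net), enum_transitivity(adj))
  }
})

test_that("total and furthest distances sum the river-based legs", {
  nodes <- c("A", "B")
  wts <- matrix(0, 3, 3, dimnames = list(c(nodes, "RIVER"), c(nodes, "RIVER")))
  wts["RIVER", "A"] <- wts["A", "RIVER"] <- 10000
  wts["RIVER", "B"] <- wts["B", "RIVER"] <- 12000
  wts["A", "B"] <- wts["B", "A"] <- 5000

  # single marine event at a node 14 km out -> 28 km out-and-back
  w14 <- matrix(c(0, 14000, 14000, 0), 2, 2,
                dimnames = list(c("A", "RIVER"), c("A", "RIVER")))
  net <- structure(list(roster = c("A", "RIVER"), nodes = "A",
                        edges = data.frame(a = character(0), b = character(0),
                                           count = integer(0)),
                        node_seq = "A"), class = "fish_network")
  expect_equal(total_distance(net, w14), 28)

  # events A,B with d(river,A)=10, d(A,B)=5, d(river,B)=12 -> 27 km
  netAB <- structure(list(roster = rownames(wts), nodes = nodes,
                          edges = data.frame(a = "A", b = "B", count = 1L),
                          node_seq = c("A", "B")), class = "fish_network")
  expect_equal(total_distance(netAB, wts), 27)

  # six-event fixture vs hand-summed legs: seq A,B,A,A(self),B,A
  net6 <- structure(list(roster = rownames(wts), nodes = nodes,
                         edges = NULL,
                         node_seq = c("A", "B", "A", "A", "B", "A")),
                    class = "fish_network")
  hand <- 10 + 5 + 5 + 0 + 5 + 5 + 10
  expect_equal(total_distance(net6, wts), hand)

  # furthest: maximum river distance over observed nodes
  expect_equal(furthest_distance(netAB, wts), 12)
  w2 <- wts; w2["RIVER", "B"] <- w2["B", "RIVER"] <- 33000
  w2["RIVER", "A"] <- w2["A", "RIVER"] <- 13600
  expect_equal(furthest_distance(netAB, w2), 33)
  # adding an observed node never decreases the result
  netA <- structure(list(roster = rownames(wts), nodes = "A"),
                    class = "fish_network")
  expect_lte(furthest_distance(netA, w2), furthest_distance(netAB, w2))
})

test_that("restricted betweenness counts distinct consecutive triples", {
  m <- node_local_metrics(toy_net(c("A", "B", "C")))
  expect_equal(m$restricted_betweenness[m$node == "B"], 1)
  expect_equal(sum(m$restricted_betweenness), 1)

  # back-and-forth A,B,A -> no restricted betweenness anywhere
  m <- node_local_metrics(toy_net(c("A", "B", "A")))
  expect_equal(sum(m$restricted_betweenness), 0)

  # random 30-event sequences vs a sliding-window oracle
  set.seed(44)
  for (rep in 1:6) {
    s <- sample(c("A", "B", "C", "D", "E"), 30, TRUE)
    net <- toy_net(s)
    m <- node_local_metrics(net)
    oracle <- stats::setNames(numeric(5), c("A", "B", "C", "D", "E"))
    for (i in 1:28) {
      tri <- s[i:(i + 2)]
      if (length(unique(tri)) == 3) oracle[tri[2]] <- oracle[tri[2]] + 1
    }
    got <- stats::setNames(m$restricted_betweenness, m$node)
    expect_equal(got[names(oracle)], oracle)
  }
})

test_that("strength satisfies the handshake identity and both self conventions", {
  set.seed(55)
  for (rep in 1:5) {
    s <- sample(c("A", "B", "C"), 20, TRUE)
    gaps <- sample(c(1, 30), 19, TRUE)  # some same-node pairs become self-edges
    net <- toy_net(s, gaps_h = c(1, gaps))
    m <- node_local_metrics(net, self_weight = 2)
    total_moves <- sum(net$edges$count)
    expect_equal(sum(m$strength), 2 * total_moves)
  }
  # self-edge counting convention: A,A self-edge gives strength 2 (default)
  # or 1 (alternative)
  net <- toy_net(c("A", "A"), gaps_h = c(1, 30))
  expect_equal(node_local_metrics(net, 2)$strength[1], 2)
  expect_equal(node_local_metrics(net, 1)$strength[1], 1)
})

test_that("metrics are invariant to reversing the event sequence", {
  set.seed(66)
  s <- sample(c("A", "B", "C", "D"), 25, TRUE)
  gaps <- c(1, sample(c(1, 30), 24, TRUE))
  net_f <- toy_net(s, gaps)
  net_r <- toy_net(rev(s), gaps)
  expect_equal(node_density(net_f), node_density(net_r))
  expect_equal(edge_density(net_f), edge_density(net_r))
  expect_equal(clustering_coefficient(net_f), clustering_coefficient(net_r))
  # strength is permutation-stable up to self-edge placement only when gaps
  # reverse symmetrically; compare the non-self edge multiset instead
  ef <- net_f$edges[net_f$edges$a != net_f$edges$b, ]
  er <- net_r$edges[net_r$edges$a != net_r$edges$b, ]
  expect_equal(ef[order(ef$a, ef$b), c("a", "b", "count")],
               er[order(er$a, er$b), c("a", "b", "count")],
               ignore_attr = TRUE)
})

test_that("group-mean local metrics standardize by ice-free days", {
  nets <- list(
    F1 = toy_net(c("A", "B", "C", "A")),
    F2 = toy_net(c("A", "B", "A"))
  )
  ret <- c(F1 = as.Date("2019-07-09"), F2 = as.Date("2019-07-29"))
  grp <- c(F1 = "above_falls", F2 = "below_falls")
  lm <- local_metrics(nets, ret, as.Date("2019-06-19"), grp)
  # F1: 20 ice-free days, strength at A = 2 (A-B and C-A) -> 0.1/day
  expect_equal(lm$strength[lm$node == "A" & lm$group == "above_falls"], 0.1)
  # F2: 40 days, strength at A = 2 -> 0.05/day
  expect_equal(lm$strength[lm$node == "A" & lm$group == "below_falls"], 0.05)
  expect_error(local_metrics(nets, c(F1 = as.Date("2019-06-19"),
                                     F2 = as.Date("2019-07-29")),
                             as.Date("2019-06-19"), grp),
               "zero ice-free days")
})
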
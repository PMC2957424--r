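test_that("minimal radius per root follows the counting-array BFS", {
  # star: each leaf covers a distinct case, the center covers none
  edges <- cbind("h", paste0("v", 1:4))
  net <- gene_network(edges)
  inc <- matrix(0L, 5, 4, dimnames = list(net$nodes, paste0("u", 1:4)))
  for (i in 1:4) inc[paste0("v", i), i] <- 1L
  inst <- build_instance(net, inc, k = 1, l = 0)
  expect_equal(min_radius_for_root(inst, "h"), 1)
  expect_equal(min_radius_for_root(inst, "v1"), 2)
  # a root covering everything is feasible at level 0
  inc0 <- inc
  inc0["h", ] <- 1L
  inst0 <- build_instance(net, inc0, k = 1, l = 0)
  expect_equal(min_radius_for_root(inst0, "h"), 0)
  # an isolated empty node never becomes feasible
  net2 <- gene_network(cbind("a", "b"), nodes = "z")
  inc2 <- matrix(c(1L, 1L, 0L), 3, 1,
                 dimnames = list(net2$nodes, "u1"))
  inc2["z", 1] <- 0L
  inst2 <- build_instance(net2, inc2, k = 1, l = 0)
  expect_identical(min_radius_for_root(inst2, "z"), Inf)
  expect_error(min_radius_for_root(inst2, "q"), "unknown node")
})

test_that("the radius scan finds the central root of a path", {
  inst <- path_instance(list(a = "u1", c = "u2"), k = 1, l = 0)
  sc <- radius_scan(inst)
  expect_equal(sc$r_min, 1)
  expect_identical(sc$v_min, "b")
  # infeasible instance: not enough total coverage anywhere
  inst2 <- path_instance(list(a = "u1"), k = 2, l = 0,
                         cases = c("u1", "u2"))
  sc2 <- radius_scan(inst2)
  expect_identical(sc2$r_min, Inf)
  expect_identical(sc2$v_min, character())
})

test_that("the solver returns all minimum-size pathways with root and radius", {
  inst <- path_instance(list(a = c("u1", "u2"), c = c("u2", "u3")),
                        k = 1, l = 0)
  dps <- solve_mrmcc(inst)
  expect_length(dps, 1)
  expect_setequal(dps[[1]]$nodes, c("a", "b", "c"))
  expect_identical(dps[[1]]$root, "b")
  expect_equal(dps[[1]]$radius, 1)
  # single-node optimum at radius 0
  inst1 <- path_instance(list(b = c("u1", "u2")), k = 1, l = 0)
  dps1 <- solve_mrmcc(inst1)
  expect_identical(dps1[[1]]$nodes, "b")
  expect_equal(dps1[[1]]$radius, 0)
  # symmetric instance keeps both tying roots
  net <- gene_network(rbind(c("a", "b"), c("b", "c"), c("c", "d")))
  inc <- matrix(0L, 4, 2, dimnames = list(net$nodes, c("u1", "u2")))
  inc["b", ] <- c(1L, 0L)
  inc["c", ] <- c(0L, 1L)
  inst2 <- build_instance(net, inc, k = 1, l = 0)
  dps2 <- solve_mrmcc(inst2)
  expect_length(dps2, 2)
  expect_setequal(vapply(dps2, function(d) d$root, ""), c("b", "c"))
  expect_identical(sort(dps2[[1]]$nodes), c("b", "c"))
  expect_error(solve_mrmcc(path_instance(list(a = "u1"), k = 3, l = 0)),
               "no connected")
})

test_that("brute force agrees with hand-checked optima", {
  inst <- path_instance(list(a = c("u1", "u2"), c = c("u2", "u3")),
                        k = 1, l = 0)
  bf <- brute_force_mcc(inst)
  expect_equal(bf$size, 3)
  inst1 <- path_instance(list(b = c("u1", "u2")), k = 1, l = 0)
  expect_equal(brute_force_mcc(inst1)$size, 1)
  infeas <- path_instance(list(a = "u1"), k = 2, l = 0)
  expect_identical(brute_force_mcc(infeas)$size, Inf)
  expect_error(brute_force_mcc(random_instance(20, 4)), "too large")
})

test_that("capped BFS matches uncapped results up to the cap", {
  withr::local_seed(41)
  for (i in 1:20) {
    inst <- random_instance(15, 6, p_inc = 0.25, k = 2, l = 1)
    full <- vapply(inst$network$nodes,
                   function(v) min_radius_for_root(inst, v), numeric(1))
    cap <- if (all(is.infinite(full))) 2 else min(full)
    capped <- vapply(inst$network$nodes,
                     function(v) min_radius_for_root(inst, v, cap = cap),
                     numeric(1))
    ok <- is.finite(full) & full <= cap
    expect_identical(capped[ok], full[ok])
    expect_true(all(is.infinite(capped[!ok])))
  }
})

test_that("the radius scan is invariant under node relabeling", {
  withr::local_seed(43)
  for (i in 1:5) {
    inst <- random_instance(14, 5, p_inc = 0.3, k = 1, l = 0)
    sc <- radius_scan(inst)
    # relabel: node i gets a fresh name, topology and sets move with it
    map <- setNames(sprintf("n%02d", sample.int(14)), inst$network$nodes)
    net2 <- gene_network(matrix(map[network_edges(inst$network)], ncol = 2),
                         nodes = unname(map))
    inc2 <- inst$inc
    rownames(inc2) <- map[rownames(inc2)]
    inst2 <- build_instance(net2, inc2, inst$k, inst$l)
    sc2 <- radius_scan(inst2)
    expect_equal(sc2$r_min, sc$r_min)
    if (is.finite(sc$r_min)) {
      expect_setequal(sc2$v_min, unname(map[sc$v_min]))
    }
  }
})
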
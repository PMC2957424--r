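test_that("instance construction reconciles genes with the network", {
  net <- gene_network(cbind("A", "B"))
  inc <- matrix(c(1L, 0L, 1L, 1L), 2, 2,
                dimnames = list(c("A", "C"), c("u1", "u2")))
  inst <- build_instance(net, inc, k = 1, l = 0)
  expect_identical(rownames(inst$inc), c("A", "B"))
  expect_equal(unname(inst$inc["A", ]), c(1L, 1L))
  expect_equal(sum(inst$inc["B", ]), 0)          # back node, empty cover set
  expect_error(build_instance(net, inc, k = 1, l = 2), "0 <= l < number")
  inc2 <- inc
  rownames(inc2) <- c("X", "Y")
  expect_error(build_instance(net, inc2, k = 1, l = 0), "no expression gene")
})

test_that("the outlier budget is the floor of the case fraction", {
  expect_equal(outlier_count(3, 0.2), 0L)
  expect_equal(outlier_count(20, 0.2), 4L)
  expect_equal(outlier_count(29, 0.2), 5L)
  expect_equal(outlier_count(10, 0), 0L)
})

test_that("cover validation checks connectivity and the outlier budget", {
  # three genes on a path; cases 1 and 3 have two dysregulated genes in
  # the set, case 2 only one: valid at k = 2, l = 1 with case 2 the outlier
  inst <- path_instance(list(a = c("c1", "c2"), b = c("c1", "c3"),
                             c = c("c3")), k = 2, l = 1)
  v <- is_connected_cover(c("a", "b", "c"), inst)
  expect_true(v$valid)
  expect_identical(v$outliers, "c2")
  # perfect coverage but disconnected set fails
  net <- gene_network(cbind(c("a", "c"), c("b", "d")))   # a-b, c-d
  inc <- matrix(1L, 4, 2, dimnames = list(letters[1:4], c("u1", "u2")))
  inst2 <- build_instance(net, inc, k = 2, l = 0)
  expect_false(is_connected_cover(c("a", "c"), inst2)$valid)
  expect_true(is_connected_cover(c("a", "b"), inst2)$valid)
  expect_identical(is_connected_cover(c("a", "b"), inst2)$outliers,
                   character())
  expect_false(is_connected_cover(character(), inst2)$valid)
})

make_hub_network <- function(n_leaves, ring_cover = 1L, hub_cover = 0L) {
  leaves <- sprintf("leaf%03d", seq_len(n_leaves))
  ring <- sprintf("ring%03d", seq_len(310))
  edges <- rbind(cbind("hub", leaves),
                 cbind(ring, c(ring[-1], ring[1])))
  net <- gene_network(edges)
  sizes <- setNames(rep(0, length(net$nodes)), net$nodes)
  sizes[ring] <- ring_cover
  sizes["hub"] <- hub_cover
  list(net = net, sizes = sizes, leaves = leaves, ring = ring)
}

test_that("hub hiding removes only high-degree, low-evidence nodes", {
  h <- make_hub_network(101)
  out <- hide_hubs(h$net, h$sizes)
  expect_identical(attr(out, "hidden"), "hub")
  expect_true(all(h$leaves %in% out$nodes))
  # degree exactly at the threshold is never removed
  h100 <- make_hub_network(100)
  out100 <- hide_hubs(h100$net, h100$sizes)
  expect_length(attr(out100, "hidden"), 0)
  # a hub whose neighborhood carries strong evidence survives
  h2 <- make_hub_network(101)
  h2$sizes[h2$leaves] <- 20        # hub's neighborhood score now top 25%
  out2 <- hide_hubs(h2$net, h2$sizes)
  expect_length(attr(out2, "hidden"), 0)
})

test_that("hub hiding respects a lowered degree threshold too", {
  withr::local_seed(13)
  for (i in 1:5) {
    inst <- random_instance(25, 6, p_edge = 0.2, p_inc = 0.3, k = 1, l = 0)
    net2 <- hide_hubs(inst$network, inst$set_sizes, hub_degree = 4,
                      hub_quantile = 0.75)
    deg <- network_degree(inst$network)
    expect_true(all(names(deg)[deg <= 4] %in% net2$nodes))
  }
})

test_that("greedy expansion adds connector nodes when needed", {
  inst <- path_instance(list(a = c("u1", "u2"), c = c("u2", "u3")),
                        k = 1, l = 0)
  dp <- expanding_greedy(inst, root = "a")
  expect_setequal(dp$nodes, c("a", "b", "c"))   # b is a pure connector
  expect_equal(dp$size, brute_force_mcc(inst)$size)
  # a root covering the whole universe stands alone
  inst2 <- path_instance(list(a = c("u1", "u2", "u3")), k = 1, l = 0)
  dp2 <- expanding_greedy(inst2, root = "a")
  expect_identical(dp2$nodes, "a")
  expect_error(expanding_greedy(inst, root = "a", allowed = c("b", "c")),
               "root is not in the allowed region")
})

test_that("greedy failure inside a too-small region returns NULL", {
  inst <- path_instance(list(a = c("u1"), c = c("u2")), k = 1, l = 0)
  expect_null(expanding_greedy(inst, root = "a", allowed = c("a", "b")))
})

test_that("gain ties break on the neighbor-coverage total", {
  # root r connects to x and y; both newly cover 2 cases, but x's
  # neighbor carries more total coverage than y's
  edges <- rbind(c("r", "x"), c("r", "y"), c("x", "x2"), c("y", "y2"))
  net <- gene_network(edges)
  cases <- paste0("u", 1:7)
  inc <- matrix(0L, 5, 7, dimnames = list(net$nodes, cases))
  # root covers nothing; x and y tie on gain 2
  inc["x", c("u1", "u2")] <- 1L
  inc["y", c("u3", "u4")] <- 1L
  inc["x2", c("u1", "u2", "u3", "u4", "u5")] <- 1L   # totals 5 behind x
  inc["y2", c("u5", "u6", "u7")] <- 1L               # totals 3 behind y
  inst <- build_instance(net, inc, k = 1, l = 3)
  dp <- expanding_greedy(inst, root = "r")
  expect_identical(dp$nodes[2], "x")
})

test_that("two-phase greedy reduces to single-phase at l = 0", {
  withr::local_seed(31)
  for (i in 1:10) {
    inst <- random_instance(12, 5, p_inc = 0.35, k = 1, l = 0)
    sc <- radius_scan(inst)
    if (is.infinite(sc$r_min)) next
    root <- sc$v_min[1]
    allowed <- neighborhood(inst, root, sc$r_min)
    a <- expanding_greedy_2phase(inst, root, allowed)
    b <- cleanup(expanding_greedy(inst, root, allowed), inst)
    expect_identical(sort(a$nodes), sort(b$nodes))
  }
})

test_that("two-phase greedy never returns a larger pathway than single-phase", {
  # u4 tempts the first run toward the far arm; the two-phase variant
  # keeps the better of the two runs
  edges <- rbind(c("r", "a"), c("a", "b"), c("r", "x"), c("x", "y"),
                 c("y", "z"))
  net <- gene_network(edges)
  cases <- paste0("u", 1:4)
  inc <- matrix(0L, 6, 4, dimnames = list(net$nodes, cases))
  inc["r", "u1"] <- 1L
  inc["a", c("u2", "u4")] <- 1L
  inc["b", "u3"] <- 1L
  inc["x", c("u2", "u3")] <- 1L
  inst <- build_instance(net, inc, k = 1, l = 1)
  one <- cleanup(expanding_greedy(inst, "r"), inst)
  two <- expanding_greedy_2phase(inst, "r")
  expect_lte(two$size, one$size)
})

test_that("cleanup strips superfluous leaves and is a fixed point", {
  inst <- path_instance(list(a = c("u1", "u2"), b = c("u1", "u2"),
                             c = c("u1")), k = 1, l = 0)
  fat <- dp_result(c("a", "b", "c"), root = "a", radius = 2,
                   k = 1, l = 0)
  slim <- cleanup(fat, inst)
  # the sweep removes a (b still covers u1, u2), then c: b alone remains
  expect_identical(slim$nodes, "b")
  again <- cleanup(slim, inst)
  expect_identical(again$nodes, slim$nodes)
  expect_error(cleanup(dp_result("c", "c", 0, 1, 0), inst),
               "valid connected")
})
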
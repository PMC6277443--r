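test_that("edge resistance is linear in length", {
  expect_equal(edge_resistance(1000, 0.04), 40)
  expect_equal(edge_resistance(1, 0.04), 0.04)
  expect_equal(edge_resistance(2500, 0.04), 100)
  expect_error(edge_resistance(0, 0.04))
  expect_error(edge_resistance(-1, 0.04))
})

single_fiber_graph <- function(L = 1000) {
  attach_electrodes(build_graph(make_web(c(0, L / 2, L, L / 2), L = L)))
}

test_that("a single spanning fiber obeys Ohm's law", {
  sol <- solve_dc(single_fiber_graph(), V = 1, rho_lin = 0.04)
  expect_true(sol$percolating)
  expect_equal(sol$total_current, 0.025, tolerance = 1e-7)
  expect_equal(sol$equivalent_resistance, 40, tolerance = 1e-7)
})

test_that("parallel spanning fibers combine as parallel resistors", {
  L <- 1000
  two <- make_web(rbind(c(0, 300, L, 300), c(0, 700, L, 700)), L = L)
  g2 <- attach_electrodes(build_graph(two))
  expect_equal(solve_dc(g2, V = 1)$equivalent_resistance, 20,
               tolerance = 1e-7)

  ten <- make_web(cbind(0, seq(50, 950, by = 100), L,
                        seq(50, 950, by = 100)), L = L)
  g10 <- attach_electrodes(build_graph(ten))
  expect_equal(sheet_resistance(g10), 4, tolerance = 1e-7)
})

test_that("a balanced Wheatstone bridge carries no bridge current", {
  # nodes: 1 in, 4 out, 2/3 the bridge corners; all arms length 25 (R = 1)
  g <- make_graph(
    x = c(0, 1, 1, 2, -1, 3), y = c(0, 1, -1, 0, 0, 0),
    type = c(rep("junction", 4), "terminal", "terminal"),
    from = c(1, 1, 2, 3, 2, 5, 4),
    to   = c(2, 3, 4, 4, 3, 1, 6),
    length = c(25, 25, 25, 25, 10, NA, NA),
    kind = c(rep("fiber", 5), "contact", "contact"),
    source = 5, sink = 6)
  sol <- solve_dc(g, V = 1, rho_lin = 0.04)
  bridge <- which(g$edges$from == 2 & g$edges$to == 3)
  expect_lt(abs(sol$edge_currents[bridge]), 1e-9 * max(abs(sol$edge_currents)))
  expect_equal(sol$equivalent_resistance, 1, tolerance = 1e-6)
})

test_that("sparse solution matches the dense brute-force oracle", {
  for (s in c(7, 19, 42)) {
    g <- random_test_graph(50, seed = s)
    sol <- solve_dc(g, V = 1)
    oracle <- dense_solve(g, V = 1)
    expect_lt(max(abs(sol$node_potentials - oracle$potentials)), 1e-9)
    expect_equal(sol$equivalent_resistance, oracle$R_eq, tolerance = 1e-9)
  }
})

test_that("Kirchhoff's current law and energy balance hold", {
  for (s in c(3, 8)) {
    web <- generate_web(L = 500, w = 1, target_T = 0.9, seed = s)
    g <- prune_dangling(attach_electrodes(build_graph(web)))
    sol <- solve_dc(g, V = 2)
    expect_lt(kcl_residual_fast(g, sol), 1e-9)
    expect_equal(sum(sol$edge_powers),
                 sol$applied_voltage * sol$total_current,
                 tolerance = 1e-9)
  }
})

test_that("doubling every edge length doubles the sheet resistance", {
  g <- random_test_graph(30, seed = 5)
  r1 <- sheet_resistance(g)
  g$edges$length <- g$edges$length * 2
  expect_equal(sheet_resistance(g), 2 * r1, tolerance = 1e-9)
})

test_that("potentials scale with V and powers with V^2", {
  g <- random_test_graph(40, seed = 2)
  s1 <- solve_dc(g, V = 1)
  s8 <- solve_dc(g, V = 8)
  expect_equal(s8$node_potentials, 8 * s1$node_potentials, tolerance = 1e-9)
  expect_equal(s8$edge_powers, 64 * s1$edge_powers, tolerance = 1e-9)
  expect_equal(edge_power(s8), s8$edge_powers)
})

test_that("swapping the electrodes preserves R_eq and negates currents", {
  g <- random_test_graph(35, seed = 9)
  s1 <- solve_dc(g, V = 1)
  gs <- g
  gs$source <- g$sink; gs$sink <- g$source
  s2 <- solve_dc(gs, V = 1)
  expect_equal(s2$equivalent_resistance, s1$equivalent_resistance,
               tolerance = 1e-9)
  expect_equal(s2$edge_currents, -s1$edge_currents, tolerance = 1e-9)
})

test_that("non-percolating webs give infinite resistance, not an error", {
  gv <- attach_electrodes(build_graph(make_web(c(5, 0, 5, 10), L = 10)))
  sol <- solve_dc(gv, V = 1)
  expect_false(sol$percolating)
  expect_identical(sol$equivalent_resistance, Inf)
  expect_true(all(sol$edge_currents == 0))
  expect_identical(sheet_resistance(gv), Inf)
})

test_that("floating components are flagged and carry no current", {
  # spanning fiber plus a crossing pair of top-bottom fibers; dropping their
  # junctions with fiber 1 leaves that pair's node electrically isolated
  web <- make_web(rbind(c(0, 1, 20, 1),              # spans left-right
                        c(3, 0, 4, 20), c(1, 0, 6, 20)), L = 20)
  keep <- web$junctions$fiber_a != 1 & web$junctions$fiber_b != 1
  web$junctions <- web$junctions[keep, , drop = FALSE]
  g <- attach_electrodes(build_graph(web))
  sol <- solve_dc(g, V = 1)
  expect_true(sol$percolating)
  jn <- which(g$nodes$type == "junction")
  expect_true(all(sol$floating[jn]))
  expect_true(all(sol$node_potentials[jn] == 0))
})

test_that("netlist export and parse are inverse", {
  g <- single_fiber_graph(1000)
  nl <- export_netlist(g, V = 1, rho_lin = 0.04)
  expect_identical(sum(grepl("^R", nl)), 3L)   # 1 fiber + 2 contact
  expect_identical(sum(grepl("^V", nl)), 1L)
  expect_true(any(nl == ".op"))
  parsed <- parse_netlist(nl)
  expect_identical(parsed$edges$from, g$edges$from)
  expect_identical(parsed$edges$to, g$edges$to)
  r <- ifelse(g$edges$kind == "fiber", 0.04 * g$edges$length,
              g$contact_resistance)
  expect_identical(parsed$edges$resistance, r)
  expect_identical(parsed$V, 1)
  expect_identical(parsed$source, g$source)
})
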
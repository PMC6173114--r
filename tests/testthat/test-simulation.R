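two_cell <- function() fixture_delta_notch(1, 2)$epithelium

test_that("two-cell synchronous dynamics match the brute-force oracle", {
  epi <- two_cell()
  tr <- run_simulation(epi, scheme = "synchronous")
  expect_false(tr$converged)
  expect_equal(tr$cycle_length, 2L)

  # trajectory states agree with the oracle state-for-state
  s <- two_cell_vec(tr$states[[1]])
  expect_equal(s, c(g1 = 0L, r1 = 0L, g2 = 0L, r2 = 0L))
  for (k in 2:length(tr$states)) {
    s <- oracle_two_cell_step(s)
    expect_equal(two_cell_vec(tr$states[[k]]), s)
  }

  # engine and oracle agree on the successor of every joint state, and the
  # two polarized states are the only stable ones
  for (r1 in 0:1) for (r2 in 0:1) for (g1 in 0:1) for (g2 in 0:1) {
    st <- epi$initial
    st[1, c("Green", "Red")] <- c(g1, r1)
    st[2, c("Green", "Red")] <- c(g2, r2)
    nxt <- step_synchronous(epi, st)
    expect_equal(two_cell_vec(nxt),
                 oracle_two_cell_step(c(g1 = g1, r1 = r1, g2 = g2, r2 = r2)))
    expect_equal(is_stable(epi, st),
                 oracle_two_cell_stable(c(g1 = g1, r1 = r1, g2 = g2, r2 = r2)))
  }
  stable <- list(c(1L, 0L), c(0L, 1L))
  for (pol in stable) {
    st <- epi$initial
    st[, "Red"] <- pol
    expect_true(is_stable(epi, st))
    tr2 <- run_simulation(clone_epithelium(epi, st), scheme = "synchronous")
    expect_true(tr2$converged)
    expect_equal(tr2$steps_to_stability, 0L)
  }
})

test_that("alpha = 1 reproduces the synchronous operator bitwise", {
  for (i in 1:50) {
    epi <- random_dn_instance(i)
    sync <- step_synchronous(epi, epi$initial)
    set.seed(i + 1000)
    async <- step_alpha_async(epi, epi$initial, alpha = 1)
    expect_identical(unclass(sync)[, ], unclass(async)[, ], info = i)
  }
})

test_that("the exact-count sampler updates round(alpha * n) cells", {
  fx <- fixture_delta_notch(10, 10)
  epi <- fx$epithelium
  st <- epi$initial
  st[, "Red"] <- 1L   # every cell pending (Red wants to flip via Green)
  set.seed(3)
  # all cells want to change; exactly 25 of 100 may
  nxt <- step_alpha_async(epi, st, alpha = 0.25)
  changed <- sum(unclass(nxt)[, "Red"] != unclass(st)[, "Red"])
  expect_equal(changed, 25L)
})

test_that("stable patterns absorb every scheme, seed and alpha", {
  fx <- fixture_delta_notch(8, 8)
  tr <- run_simulation(fx$epithelium,
                       simulation_config("alpha", alpha = 0.25, seed = 4,
                                         max_steps = 2000))
  expect_true(tr$converged)
  stable <- tr$states[[length(tr$states)]]
  expect_true(is_stable(fx$epithelium, stable))
  expect_equal(unclass(step_synchronous(fx$epithelium, stable))[, ],
               unclass(stable)[, ])
  for (a in c(0.1, 0.5, 1)) {
    set.seed(a * 100)
    expect_equal(unclass(step_alpha_async(fx$epithelium, stable, a))[, ],
                 unclass(stable)[, ])
  }
  set.seed(8)
  expect_equal(unclass(step_alpha_async(fx$epithelium, stable, 0.4,
                                        sampling = "bernoulli"))[, ],
               unclass(stable)[, ])
})

test_that("identical seed gives an identical trajectory", {
  fx <- fixture_delta_notch(12, 12)
  cfg <- simulation_config("alpha", alpha = 0.25, seed = 17, max_steps = 2000)
  t1 <- run_simulation(fx$epithelium, cfg)
  t2 <- run_simulation(fx$epithelium, cfg)
  expect_equal(t1$steps, t2$steps)
  expect_identical(lapply(t1$states, unclass), lapply(t2$states, unclass))
  t3 <- run_simulation(fx$epithelium,
                       simulation_config("alpha", alpha = 0.25, seed = 18,
                                         max_steps = 2000))
  expect_false(identical(lapply(t1$states, unclass), lapply(t3$states, unclass)))
})

test_that("trajectory bookkeeping: step counts, convergence flags, change log", {
  fx <- fixture_delta_notch(6, 6)
  cfg <- simulation_config("alpha", alpha = 0.25, seed = 2, max_steps = 2000)
  tr <- run_simulation(fx$epithelium, cfg)
  expect_true(tr$converged)
  expect_equal(tr$steps_to_stability, tr$steps)
  expect_length(tr$changed_cells, tr$steps)
  expect_equal(length(tr$states), tr$steps + 1L)
  # the change log matches the recorded states (Red is the only internal)
  for (k in seq_len(tr$steps)) {
    a <- unclass(tr$states[[k]]); b <- unclass(tr$states[[k + 1]])
    expect_equal(sum(a[, "Red"] != b[, "Red"]), tr$changed_cells[k], info = k)
  }
  # record = "last" keeps only the endpoints, same outcome
  tr2 <- run_simulation(fx$epithelium, cfg, record = "last")
  expect_equal(tr2$steps, tr$steps)
  expect_length(tr2$states, 2L)
  expect_equal(unclass(tr2$states[[2]])[, ],
               unclass(tr$states[[length(tr$states)]])[, ])
  # max_steps bound respected when nothing converges
  sync <- run_simulation(fixture_delta_notch(10, 10)$epithelium,
                         simulation_config("synchronous", max_steps = 20))
  expect_lte(sync$steps, 20L)
  expect_false(sync$converged)
})

test_that("clones continue the original trajectory and copy deeply", {
  epi <- two_cell()
  full <- run_simulation(epi, simulation_config("synchronous", max_steps = 6))
  mid <- full$states[[2]]
  clone <- clone_epithelium(epi, mid)
  cont <- run_simulation(clone, simulation_config("synchronous", max_steps = 4))
  expect_equal(unclass(cont$states[[2]])[, ], unclass(full$states[[3]])[, ])

  # deep copy: edits to the clone leave the original untouched
  topo <- hex_topology(4, 4)
  m <- logical_model(c(Grk = 1, Out = 1), inputs = "Grk",
                     functions = list(Out = "Grk"), name = "pos")
  orig <- epithelium(topo, m, positional = list(Grk = 1))
  cl <- clone_epithelium(orig, orig$initial)
  cl <- set_positional_input(cl, "Grk", 0)
  expect_true(all(orig$positional$Grk == 1L))
  expect_true(all(cl$positional$Grk == 0L))

  # swapping the integration rule on a cloned stable pattern re-patterns it
  fx <- fixture_delta_notch(10, 10)
  tr <- run_simulation(fx$epithelium,
                       simulation_config("alpha", 0.25, seed = 5,
                                         max_steps = 2000), record = "last")
  expect_true(tr$converged)
  pat <- tr$states[[2]]
  swapped <- epithelium(fx$epithelium$topology, fx$epithelium$models[[1]],
                        integration = list(Green = "Red>=1 [1:1] all"),
                        initial = unclass(pat)[, ])
  expect_false(is_stable(swapped, swapped$initial))
  tr2 <- run_simulation(swapped, simulation_config("alpha", 0.25, seed = 5,
                                                   max_steps = 5000),
                        record = "last")
  expect_true(tr2$converged)
  expect_false(identical(unclass(tr2$states[[2]])[, "Red"],
                         unclass(pat)[, "Red"]))
})

test_that("configuration validation rejects out-of-range settings", {
  expect_error(simulation_config("alpha", alpha = 0), "alpha")
  expect_error(simulation_config("alpha", alpha = 1.2, seed = 1), "alpha")
  expect_error(simulation_config("alpha", alpha = 0.5), "seed")
  expect_error(simulation_config("synchronous", max_steps = 0), "max_steps")
  expect_error(step_alpha_async(two_cell(), alpha = 2), "alpha")
})
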
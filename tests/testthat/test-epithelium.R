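# 5x4 lateral-inhibition fixture (2-component cells) used throughout.
small_dn <- function(rule = "contact1", wrap = "none", w = 5, h = 4)
  fixture_delta_notch(w, h, wrap = wrap, rule = rule)$epithelium

# Paint Red over explicit cells of an all-zero state.
with_red <- function(epi, cells) {
  st <- epi$initial
  if (length(cells)) st[cells, "Red"] <- 1L
  st
}

idx0 <- function(epi, col, row) row * epi$topology$width + col + 1L

test_that("integration input takes the highest satisfied rule level, else 0", {
  epi <- small_dn()
  # two of the six neighbours of (2,1) Red -> contact rule fires
  nb <- hex_neighbors(epi$topology, c(2, 1))
  cells <- nb[1:2, "row"] * 5 + nb[1:2, "col"] + 1L
  st <- with_red(epi, cells)
  expect_equal(eval_integration_input(epi, st, c(2, 1), "Green"), 1L)
  # no Red anywhere: zero signal
  expect_equal(eval_integration_input(epi, with_red(epi, integer()), c(2, 1), "Green"), 0L)
  expect_error(eval_integration_input(epi, st, c(2, 1), "Red"),
               "not declared as an integration input")
})

test_that("the all quantifier requires every cell of a non-empty band", {
  epi <- small_dn(rule = "contactall")
  nb <- hex_neighbors(epi$topology, c(0, 0))   # corner: truncated band
  cells <- nb[, "row"] * 5 + nb[, "col"] + 1L
  st <- with_red(epi, cells)
  expect_equal(eval_integration_input(epi, st, c(0, 0), "Green"), 1L)
  # one neighbour short: rule no longer satisfied
  st2 <- with_red(epi, cells[-1])
  expect_equal(eval_integration_input(epi, st2, c(0, 0), "Green"), 0L)
  # empty band (isolated single-cell grid): 'all' is vacuously false
  lone <- fixture_delta_notch(1, 1, rule = "contactall")$epithelium
  expect_equal(eval_integration_input(lone, lone$initial, c(0, 0), "Green"), 0L)
})

test_that("multi-level integration rules resolve highest level first", {
  topo <- hex_topology(4, 4)
  m <- logical_model(c(sig = 2, A = 1), inputs = "sig",
                     functions = list(A = "sig>=1"), name = "grad")
  epi <- epithelium(topo, m, integration = list(
    sig = list("2" = "A>=1 [1:1] atleast 3", "1" = "A>=1 [1:1] atleast 1")))
  st <- epi$initial
  nb <- hex_neighbors(topo, c(1, 1))
  st[nb[1:3, "row"] * 4 + nb[1:3, "col"] + 1L, "A"] <- 1L
  expect_equal(eval_integration_input(epi, st, c(1, 1), "sig"), 2L)
  st2 <- epi$initial
  st2[nb[1, "row"] * 4 + nb[1, "col"] + 1L, "A"] <- 1L
  expect_equal(eval_integration_input(epi, st2, c(1, 1), "sig"), 1L)
})

test_that("resolve_inputs sets positional maps and integration values", {
  # three-level positional gradient painted in row bands
  topo <- hex_topology(6, 6)
  m <- logical_model(c(Grk = 2, Out = 1), inputs = "Grk",
                     functions = list(Out = "Grk>=2"), name = "pos")
  epi <- epithelium(topo, m,
                    positional = list(Grk = list(default = 0, regions = list(
                      list(rows = c(0, 1), level = 2),
                      list(rows = c(2, 3), level = 1)))))
  st <- resolve_inputs(epi)
  expect_equal(unname(st[idx0(epi, 3, 0), "Grk"]), 2L)
  expect_equal(unname(st[idx0(epi, 3, 2), "Grk"]), 1L)
  expect_equal(unname(st[idx0(epi, 3, 5), "Grk"]), 0L)
  expect_equal(unclass(st)[, "Grk"], epi$positional$Grk)

  # all-zero internal state: every integration input 0
  dn <- small_dn()
  st <- resolve_inputs(dn, dn$initial)
  expect_true(all(st[, "Green"] == 0L))

  # contact rule against a per-cell neighbour-count oracle
  set.seed(42)
  red_cells <- sample(20, 7)
  st0 <- with_red(dn, red_cells)
  resolved <- resolve_inputs(dn, st0)
  adj <- adjacency_from_api(dn$topology)
  for (i in 1:20) {
    expected <- as.integer(any(adj[[i]] %in% red_cells))
    expect_equal(unname(resolved[i, "Green"]), expected, info = i)
  }
})

test_that("resolve_inputs is idempotent and ignores input values of its argument", {
  dn <- small_dn("dist3-12", w = 6, h = 6)
  set.seed(5)
  st <- with_red(dn, sample(36, 14))
  r1 <- resolve_inputs(dn, st)
  expect_equal(resolve_inputs(dn, r1)[, ], r1[, ])
  # scrambling inputs beforehand changes nothing: only internals matter
  st2 <- st
  st2[, "Green"] <- sample(0:1, 36, replace = TRUE)
  expect_equal(resolve_inputs(dn, st2)[, ], r1[, ])
})

test_that("integration inputs are local to the distance band", {
  dn <- small_dn("dist3-12", w = 9, h = 8)
  set.seed(9)
  st <- with_red(dn, sample(72, 20))
  base <- resolve_inputs(dn, st)
  cell <- c(2, 2)
  idx <- idx0(dn, 2, 2)
  far <- cells_at_distance(dn$topology, cell, 4, 20)
  expect_gt(nrow(far), 0)
  for (k in 1:5) {
    st2 <- st
    pick <- far[sample(nrow(far), 1), ]
    j <- idx0(dn, pick["col"], pick["row"])
    st2[j, "Red"] <- 1L - st2[j, "Red"]
    expect_equal(unname(resolve_inputs(dn, st2)[idx, "Green"]),
                 unname(base[idx, "Green"]))
  }
})

test_that("perturbations clamp their region and stay clamped through updates", {
  dn <- small_dn()
  ko <- epithelium(dn$topology, dn$models[[1]],
                   integration = list(Green = "Red>=1 [1:1] atleast 1"),
                   perturbations = list(perturbation("Red", 0L)))
  st <- apply_perturbations(ko, with_red(ko, 1:5))
  expect_true(all(st[, "Red"] == 0L))
  after <- step_synchronous(ko, st)
  expect_true(all(after[, "Red"] == 0L))

  # ectopic clone region: fixed at max inside the region only
  clone <- epithelium(dn$topology, dn$models[[1]],
                      integration = list(Green = "Red>=1 [1:1] atleast 1"),
                      perturbations = list(
                        perturbation("Red", 1L, cols = c(0, 1), rows = c(0, 1))))
  st <- apply_perturbations(clone, clone$initial)
  inside <- region_cells(clone$topology, c(0, 1), c(0, 1))
  expect_true(all(st[inside, "Red"] == 1L))
  expect_true(all(st[-inside, "Red"] == 0L))

  # idempotent; disjoint clamps commute
  expect_equal(apply_perturbations(clone, st)[, ], st[, ])
  two <- list(perturbation("Red", 1L, cols = c(0, 0)),
              perturbation("Red", 0L, cols = c(3, 4)))
  e2 <- epithelium(dn$topology, dn$models[[1]],
                   integration = list(Green = "Red>=1 [1:1] atleast 1"),
                   perturbations = two)
  e3 <- epithelium(dn$topology, dn$models[[1]],
                   integration = list(Green = "Red>=1 [1:1] atleast 1"),
                   perturbations = rev(two))
  s0 <- with_red(e2, 1:20)
  expect_equal(apply_perturbations(e2, s0)[, ], apply_perturbations(e3, s0)[, ])

  # empty perturbation list: unchanged
  expect_equal(apply_perturbations(dn, s0)[, ], s0[, ])
})

test_that("validation reports invariant breaches as findings", {
  dn <- small_dn()
  expect_length(validate_epithelium(dn), 0)

  m <- dn$models[[1]]
  both <- epithelium(dn$topology, m,
                     positional = list(Green = 0),
                     integration = list(Green = "Red>=1 [1:1] atleast 1"))
  expect_match(validate_epithelium(both), "both positional and integration",
               all = FALSE)

  undeclared <- epithelium(dn$topology, m)
  expect_match(validate_epithelium(undeclared), "neither positional nor integration",
               all = FALSE)

  # integration atom naming an input component: signals must be internal
  selfref <- epithelium(dn$topology, m,
                        integration = list(Green = "Green>=1 [1:1] atleast 1"))
  expect_match(validate_epithelium(selfref), "not an internal component",
               all = FALSE)

  overlap <- epithelium(dn$topology, m,
                        integration = list(Green = "Red>=1 [1:1] atleast 1"),
                        perturbations = list(
                          perturbation("Red", 1L, cols = c(0, 2)),
                          perturbation("Red", 0L, cols = c(2, 4))))
  expect_match(validate_epithelium(overlap), "overlapping", all = FALSE)

  badlevel <- epithelium(dn$topology, m,
                         integration = list(Green = "Red>=2 [1:1] atleast 1"))
  expect_match(validate_epithelium(badlevel), "above its maximum", all = FALSE)

  expect_error(run_simulation(undeclared, scheme = "synchronous"), "invalid")
})

test_that("heterogeneous tissues treat missing components as silent", {
  topo <- hex_topology(4, 2)
  sender <- logical_model(c(Green = 1, Red = 1), inputs = "Green",
                          functions = list(Red = "!Green"), name = "sender")
  mute <- logical_model(c(Green = 1, Quiet = 1), inputs = "Green",
                        functions = list(Quiet = "Quiet"), name = "mute")
  epi <- epithelium(topo, list(sender = sender, mute = mute),
                    assignment = list(list(model = "sender"),
                                      list(model = "mute", cols = c(2, 3))),
                    integration = list(Green = "Red>=1 [1:1] atleast 1"))
  expect_length(validate_epithelium(epi), 0)
  st <- epi$initial
  expect_true(all(is.na(st[region_cells(topo, cols = c(2, 3)), "Red"])))
  st[idx0(epi, 1, 0), "Red"] <- 1L
  resolved <- resolve_inputs(epi, st)
  # a mute neighbour never satisfies a Red>=1 atom; the sender at (1,0) does
  expect_equal(unname(resolved[idx0(epi, 2, 0), "Green"]), 1L)
  expect_equal(unname(resolved[idx0(epi, 3, 0), "Green"]), 0L)
})
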
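test_that("diagram construction validates its inputs", {
  expect_s3_class(fig1b_diagram(), "selection_diagram")
  expect_error(
    selection_diagram(c("A", "Y"), c("A -> Y", "Y -> A"), "A", "Y"),
    "cycle")
  expect_error(
    selection_diagram(c("A", "Y"), c("A -> Y", "Z -> Y"), "A", "Y"),
    "not declared")
  expect_error(
    selection_diagram(c("A", "Y"), "A -> Y", "A", "A"),
    "must differ")
  expect_error(
    selection_diagram(c("A", "Y"), "A -> Y", "A", "Y", s_pointed = "Q"),
    "s_pointed")
  # empty s_pointed is a valid diagram
  expect_s3_class(selection_diagram(c("A", "Y"), "A -> Y", "A", "Y"),
                  "selection_diagram")
})

test_that("d-separation answers the printed selection-diagram queries", {
  d <- fig1b_diagram()
  # conditioning on both shifted covariates blocks every S -> Y path
  expect_true(d_separated(d, c("S_Z1", "S_Z2"), "Y", c("Z1", "Z2")))
  # unconditionally the path S_Z1 -> Z1 -> Y is open
  expect_false(d_separated(d, c("S_Z1", "S_Z2"), "Y"))
  # disconnected components are always separated
  iso <- selection_diagram(c("A", "Y", "W"), "A -> Y", "A", "Y")
  expect_true(d_separated(iso, "W", "Y"))
  expect_true(d_separated(iso, "W", "Y", "A"))
  expect_error(d_separated(d, "Z1", "Y", "Z1"), "disjoint")
})

test_that("reachability engine agrees with the path-enumeration oracle", {
  withr::local_seed(100)
  n_checked <- 0L
  for (rep in 1:300) {
    n_nodes <- sample(3:6, 1)
    g <- random_dag_edges(n_nodes, p = runif(1, 0.2, 0.6))
    diag <- selection_diagram(g$nodes, g$edges,
                              exposure = g$nodes[1], outcome = g$nodes[2])
    q <- random_query(g$nodes)
    got <- d_separated(diag, q$x, q$y, q$z)
    want <- oracle_d_separated(g$edges, q$x, q$y, q$z)
    if (got != want) {
      fail(sprintf("disagreement on DAG [%s] query %s _||_ %s | {%s}",
                   paste(g$edges$from, "->", g$edges$to, collapse = ", "),
                   q$x, q$y, paste(q$z, collapse = ",")))
    }
    n_checked <- n_checked + 1L
  }
  expect_equal(n_checked, 300L)
})

test_that("transport classification reproduces the three canonical diagrams", {
  # confounder + effect modifier both shifted: recalibrate on both
  tc <- transport_class(fig1b_diagram(), measured = c("Z1", "Z2"))
  expect_equal(tc$category, "via_recalibration")
  expect_setequal(tc$adjustment_set, c("Z1", "Z2"))
  # S into the exposure only: directly transportable, no target data needed
  expect_equal(transport_class(fig2a_diagram(), measured = character())$category,
               "direct")
  # S into the outcome: the rule gives no guarantee, whatever is measured
  expect_equal(transport_class(fig2b_diagram(), measured = "Z")$category,
               "not_identified_by_rule")
  expect_equal(transport_class(fig2b_diagram(), measured = character())$category,
               "not_identified_by_rule")
})

test_that("classification edge cases and invariants hold", {
  # no S nodes at all: the populations share one generating process
  no_s <- selection_diagram(c("A", "Y", "Z"),
                            c("Z -> A", "Z -> Y", "A -> Y"), "A", "Y")
  expect_equal(transport_class(no_s)$category, "direct")
  # caller-asserted target data makes the effect trivially transportable
  expect_equal(transport_class(fig1b_diagram(), measured = c("Z1", "Z2"),
                               target_has_study_data = TRUE)$category,
               "trivial")
  # monotone in measurement: more measured covariates never downgrades
  d <- fig1b_diagram()
  ranks <- c(not_identified_by_rule = 0, via_recalibration = 1,
             direct = 2, trivial = 3)
  r_small <- ranks[transport_class(d, measured = "Z1")$category]
  r_big <- ranks[transport_class(d, measured = c("Z1", "Z2"))$category]
  expect_gte(r_big, r_small)
  expect_equal(transport_class(d, measured = "Z1")$category,
               "not_identified_by_rule")
  # adjustment set excludes exposure/outcome by construction
  expect_error(transport_class(d, measured = c("Z1", "Y")), "exposure/outcome")
})

test_that("classification is invariant to node relabeling", {
  relabeled <- selection_diagram(
    nodes = c("treat", "out", "conf", "mod"),
    edges = c("conf -> treat", "conf -> out", "treat -> out", "mod -> out"),
    exposure = "treat", outcome = "out", s_pointed = c("conf", "mod")
  )
  tc1 <- transport_class(fig1b_diagram(), measured = c("Z1", "Z2"))
  tc2 <- transport_class(relabeled, measured = c("conf", "mod"))
  expect_equal(tc1$category, tc2$category)
  expect_equal(length(tc1$adjustment_set), length(tc2$adjustment_set))
})

test_that("minimal adjustment sets are smallest-first with lexicographic ties", {
  # Z1 alone suffices; {Z1, Z2} also works but is not minimal
  d <- selection_diagram(
    nodes = c("A", "Y", "Z1", "Z2"),
    edges = c("Z1 -> Y", "Z1 -> Z2", "A -> Y"),
    exposure = "A", outcome = "Y", s_pointed = "Z1"
  )
  tc <- transport_class(d, measured = c("Z2", "Z1"))
  expect_equal(tc$adjustment_set, "Z1")
})

test_that("edge-list files round-trip through read_diagram", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# canonical confounded triangle", "Z1 -> A", "Z1 -> Y",
               "", "A -> Y", "Z2 -> Y"), path)
  d <- read_diagram(path, exposure = "A", outcome = "Y",
                    s_pointed = c("Z1", "Z2"))
  expect_setequal(d$nodes, c("A", "Y", "Z1", "Z2"))
  expect_equal(nrow(d$edges), 4L)
  expect_equal(transport_class(d, measured = c("Z1", "Z2"))$category,
               "via_recalibration")
})
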
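K2 <- simplicial_complex(list(c(1, 2, 3), c(2, 3, 4)))

test_that("structure vectors reproduce the two-triangle worked example", {
  expect_equal(fsv(K2)$values, c(1L, 1L, 2L))   # q-ascending; [2,1,1] descending
  expect_equal(ssv(K2)$values, c(2L, 2L, 2L))
  expect_equal(tsv(K2)$values, c(0.5, 0.5, 0))  # [0,0.5,0.5] descending
})

test_that("ssv counts simplices of dimension >= q", {
  K <- simplicial_complex(list(c(0), c(1, 2)))
  expect_equal(ssv(K)$values, c(2L, 1L))
  K1 <- simplicial_complex(list(c(1, 2, 3)))
  expect_equal(ssv(K1)$values, c(1L, 1L, 1L))
  expect_equal(fsv(K1)$values, c(1L, 1L, 1L))
})

test_that("tsv is zero when every eligible simplex is isolated and matches chain oracle", {
  # disjoint pair: each its own component at every level
  Kd <- simplicial_complex(list(c(0, 1), c(2, 3)))
  expect_equal(tsv(Kd)$values, c(0, 0))
  # chain of three pairwise 1-near 2-simplices: one component over three simplices
  Kc <- simplicial_complex(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))
  expect_equal(tsv(Kc)$values[2], 1 - 1 / 3)
})

test_that("topological entropy matches hand-evaluated and degenerate cases", {
  # participation in dim-2 simplices of K2: v1 1, v2 2, v3 2, v4 1 (sum 6)
  expected <- ((2 * (1 / 6) * log(6) + 2 * (1 / 3) * log(3))) / log(4)
  e <- topological_entropy(K2)
  expect_equal(e$values[3], expected, tolerance = 1e-12)
  expect_equal(round(e$values[3], 4), 0.9591)
  # no simplex of dimension exactly 0 or 1 in K2: undefined marker
  expect_true(all(is.nan(e$values[1:2])))

  # uniform participation: single 1-simplex at q=1 has entropy exactly 1
  K1 <- simplicial_complex(list(c(1, 2)))
  expect_equal(topological_entropy(K1)$values[2], 1)
  # single participating vertex: zero by convention
  K0 <- simplicial_complex(list(c(7)))
  expect_equal(topological_entropy(K0)$values[1], 0)
})

test_that("entropy cumulative participation option counts dim >= q", {
  # exact mode: q=1 undefined for K2; cumulative mode: counts the 2-simplices
  e_cum <- topological_entropy(K2, participation = "cumulative")
  expect_false(anyNA(e_cum$values))
  expect_true(all(e_cum$values >= 0 & e_cum$values <= 1))
})

test_that("per-dimension counts and shared-face counts follow their definitions", {
  expect_equal(simplex_count_per_dim(K2)$values, c(0L, 0L, 2L))
  K <- simplicial_complex(list(c(0), c(1, 2)))
  expect_equal(simplex_count_per_dim(K)$values, c(1L, 1L))
  K1 <- simplicial_complex(list(c(1, 2, 3)))
  expect_equal(simplex_count_per_dim(K1)$values, c(0L, 0L, 1L))

  expect_equal(shared_face_count(K2)$values, c(1L, 1L, 0L))
  Kd <- simplicial_complex(list(c(0, 1), c(2, 3)))
  expect_equal(shared_face_count(Kd)$values, c(0L, 0L))
  # three simplices pairwise sharing one vertex
  Kp <- simplicial_complex(list(c(1, 2), c(2, 3), c(3, 1)))
  expect_equal(shared_face_count(Kp)$values[1], 3L)
  # exact mode counts pairs at exactly q
  expect_equal(shared_face_count(K2, count = "exact")$values, c(0L, 1L, 0L))
})

test_that("graded_parameters selects series, defaults to all, rejects unknown names", {
  b <- graded_parameters(K2, c("FSV", "SSV", "TSV"))
  expect_named(b$series, c("FSV", "SSV", "TSV"))
  expect_true(all(vapply(b$series, function(s) length(s$values), integer(1)) == 3L))

  b_all <- graded_parameters(K2)
  expect_length(b_all$series, 6L)

  # names are case-insensitive, matching the lower-case API convention
  b_lc <- graded_parameters(K2, c("fsv", "entropy"))
  expect_named(b_lc$series, c("FSV", "Entropy"))

  expect_error(graded_parameters(K2, "XSV"), "unknown series")
})

test_that("tidy table has fixed columns, extra constants, and round-trips series", {
  tab <- to_tidy_table(graded_parameters(K2), c(Network = "toy"))
  expect_equal(nrow(tab), 18L)  # 6 series x 3 levels
  expect_equal(names(tab), c("Vector", "q", "Value", "Network"))
  expect_true(all(tab$Network == "toy"))

  # projection identity: FSV rows reproduce fsv values
  fsv_rows <- tab[tab$Vector == "FSV", ]
  expect_equal(fsv_rows$Value[order(fsv_rows$q)], as.numeric(fsv(K2)$values))

  tab1 <- to_tidy_table(graded_parameters(K2, "SSV"))
  expect_equal(nrow(tab1), K2$d_max + 1L)

  expect_error(to_tidy_table(graded_parameters(K2), c(Value = "x")), "reserved")
  # undefined entropy levels are NA, dropped on request
  expect_equal(sum(is.na(tab$Value)), 2L)
  tab_drop <- to_tidy_table(graded_parameters(K2), drop_undefined = TRUE)
  expect_false(anyNA(tab_drop$Value))
})

test_that("structure-vector identities hold on random complexes", {
  set.seed(11)
  for (rep in 1:20) {
    K <- simplicial_complex(random_simplex_list())
    q_vals <- fsv(K)$values
    n_vals <- ssv(K)$values
    cnt <- simplex_count_per_dim(K)$values
    expect_true(all(q_vals >= 1 & q_vals <= n_vals))
    expect_true(all(diff(n_vals) <= 0))
    expect_equal(n_vals[1], K$m)
    expect_gte(n_vals[K$d_max + 1], 1L)
    expect_equal(n_vals, rev(cumsum(rev(cnt))))  # SSV[q] = sum_{q'>=q} counts
    t_vals <- tsv(K)$values
    expect_true(all(t_vals >= 0 & t_vals < 1))
    e_vals <- topological_entropy(K)$values
    e_def <- e_vals[!is.nan(e_vals)]
    expect_true(all(e_def >= -1e-12 & e_def <= 1 + 1e-12))
  }
})
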
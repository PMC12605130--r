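K2 <- simplicial_complex(list(c(1, 2, 3), c(2, 3, 4)))

test_that("construction maps labels, removes within-simplex duplicates, handles duplicates", {
  expect_equal(K2$m, 2L)
  expect_equal(K2$n, 4L)
  expect_equal(K2$d_max, 2L)
  expect_equal(K2$labels, c("1", "2", "3", "4"))

  # repeated vertex inside one record collapses to a set
  K <- simplicial_complex(list(c(1, 1, 2)))
  expect_equal(K$m, 1L)
  expect_equal(K$dims, 1L)
  expect_equal(K$simplices[[1]], c(1L, 2L))

  # duplicate simplices retained by default, collapsed on request
  Kd <- simplicial_complex(list(c(0), c(0)))
  expect_equal(Kd$m, 2L)
  expect_equal(Kd$dims, c(0L, 0L))
  Kc <- simplicial_complex(list(c(0), c(0)), keep_duplicates = FALSE)
  expect_equal(Kc$m, 1L)

  expect_error(simplicial_complex(list()), "non-empty")
  expect_error(simplicial_complex(list(c(1, 2), character(0))), "simplex 2")
})

test_that("clique complex of a graph enumerates maximal cliques deterministically", {
  tri <- complex_from_adjacency(triangle_adjacency())
  expect_equal(tri$m, 1L)
  expect_equal(tri$simplices[[1]], 1:3)

  # path 0-1-2-3: three maximal edges
  p <- matrix(0, 4, 4)
  p[cbind(1:3, 2:4)] <- 1
  p <- p + t(p)
  Kp <- complex_from_adjacency(p)
  expect_equal(Kp$simplices, list(c(1L, 2L), c(2L, 3L), c(3L, 4L)))

  # isolated vertices become 0-simplices
  Kz <- complex_from_adjacency(matrix(0, 3, 3))
  expect_equal(Kz$m, 3L)
  expect_equal(Kz$dims, rep(0L, 3))

  expect_error(complex_from_adjacency(matrix(0, 2, 3)), "square")
  asym <- matrix(c(0, 1, 0, 0), 2, 2)
  expect_error(complex_from_adjacency(asym), "symmetric")
  expect_error(complex_from_adjacency(-triangle_adjacency()), "non-negative")
})

test_that("incidence and connectivity matrices follow their definitions", {
  lam <- incidence_matrix(K2)
  expect_equal(unname(lam), rbind(c(1L, 1L, 1L, 0L), c(0L, 1L, 1L, 1L)))
  expect_equal(rowSums(lam), lengths(K2$simplices))

  pi_mat <- connectivity_matrix(K2)
  expect_equal(unname(pi_mat), rbind(c(2L, 1L), c(1L, 2L)))

  # disjoint simplices have off-diagonal -1
  Kd <- simplicial_complex(list(c(0, 1), c(2, 3)))
  expect_equal(connectivity_matrix(Kd)[1, 2], -1L)
})

test_that("q-nearness reads the shared-face dimension", {
  expect_equal(q_nearness(K2, 1, 2), 1L)
  expect_equal(q_nearness(K2, 1, 1), 2L)  # self-nearness is own dimension
  Kd <- simplicial_complex(list(c(0, 1), c(2, 3)))
  expect_equal(q_nearness(Kd, 1, 2), -1L)
  expect_error(q_nearness(K2, 0, 1), "index")
  expect_error(q_nearness(K2, 1, 3), "index")
})

test_that("component counts and labelings match the two-triangle example", {
  expect_equal(q_connected_components(K2, 2), 2L)
  expect_equal(q_connected_components(K2, 1), 1L)
  expect_equal(q_connected_components(K2, 0), 1L)
  expect_error(q_connected_components(K2, -1), "q must be")
  expect_error(q_connected_components(K2, 3), "q must be")

  expect_equal(q_connected_components_labeled(K2, 2)$components, list(1L, 2L))
  expect_equal(q_connected_components_labeled(K2, 1)$components, list(c(1L, 2L)))
})

test_that("illustrative four-simplex complex matches its stated structure", {
  Fx <- illustrative_complex()
  expect_equal(Fx$m, 4L)
  expect_equal(Fx$n, 7L)
  pi_mat <- connectivity_matrix(Fx)
  expect_equal(pi_mat[1, 1], 3L)
  expect_equal(pi_mat[1, 2], 2L)
  # sigma1 and sigma3 share only one vertex
  expect_equal(q_nearness(Fx, 1, 3), 0L)
  expect_equal(
    vapply(0:3, function(q) q_connected_components(Fx, q), integer(1)),
    c(1L, 2L, 2L, 2L)
  )
  # sigma1..sigma3 form one 1-connected component, sigma4 another
  lab1 <- q_connected_components_labeled(Fx, 1)
  expect_true(any(
    vapply(lab1$components, function(g) setequal(g, 1:3), logical(1))
  ))
})

test_that("cached all-levels components agree with the BFS oracle on random complexes", {
  set.seed(42)
  for (rep in 1:60) {
    sl <- random_simplex_list()
    K <- simplicial_complex(sl)
    for (q in 0:K$d_max) {
      expect_equal(
        q_connected_components(K, q),
        oracle_component_count(sl, q),
        info = sprintf("rep %d q %d", rep, q)
      )
    }
  }
})

test_that("component structure satisfies refinement, eligibility and symmetry invariants", {
  set.seed(7)
  for (rep in 1:25) {
    sl <- random_simplex_list()
    K <- simplicial_complex(sl)
    pi_mat <- connectivity_matrix(K)
    expect_true(isSymmetric(pi_mat))
    expect_equal(diag(pi_mat), K$dims)
    n_elig_prev <- Inf
    for (q in 0:K$d_max) {
      lab <- q_connected_components_labeled(K, q)
      elig <- sort(unlist(lab$components))
      expect_equal(elig, which(K$dims >= q))
      expect_lte(length(elig), n_elig_prev)
      n_elig_prev <- length(elig)
      if (q < K$d_max) {
        # every (q+1)-component lies inside exactly one q-component
        for (grp in q_connected_components_labeled(K, q + 1)$components) {
          parents <- unique(lab$membership[as.character(grp)])
          expect_length(parents, 1)
        }
      }
    }
  }
})

test_that("identical inputs give identical matrices and labelings", {
  sl <- list(c(1, 5, 6), c(2, 5), c(6, 7, 8), c(1, 2))
  a <- simplicial_complex(sl)
  b <- simplicial_complex(sl)
  expect_identical(incidence_matrix(a), incidence_matrix(b))
  expect_identical(connectivity_matrix(a), connectivity_matrix(b))
  for (q in 0:a$d_max) {
    expect_identical(
      q_connected_components_labeled(a, q)$components,
      q_connected_components_labeled(b, q)$components
    )
  }
})
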
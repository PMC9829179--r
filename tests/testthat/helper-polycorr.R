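# shared fixtures, all generated in code

# tiny noisy triangle dataset
tiny_triangle_data <- function(N = 20, sides = c(50, 60, 15),
                               sigma_xy = c(10, 10, 15), sigma_z = c(20, 20, 30),
                               seed = 42) {
  des <- polygon_design(triangle_template(sides[1], sides[2], sides[3]),
                        sigma_xy, sigma_z,
                        subsets = list(name = "sim", N = N))
  simulate_polygons(des, seed = seed)
}

# random canonical triangle template
random_triangle <- function() {
  repeat {
    l <- runif(3, 5, 100)
    if (triangle_inequality_holds(l)) return(triangle_template(l[1], l[2], l[3]))
  }
}

# brute-force random-walk Metropolis targeting an arbitrary 1D log density;
# independent oracle for the Gibbs conditionals
mh_1d <- function(logf, x0, n, step, lower = -Inf, upper = Inf) {
  x <- numeric(n)
  cur <- x0
  lcur <- logf(cur)
  for (i in seq_len(n)) {
    prop <- cur + rnorm(1, 0, step)
    if (prop > lower && prop < upper) {
      lprop <- logf(prop)
      if (is.finite(lprop) && log(runif(1)) < lprop - lcur) {
        cur <- prop; lcur <- lprop
      }
    }
    x[i] <- cur
  }
  x
}

expect_rotation_matrix <- function(R) {
  expect_equal(crossprod(R), diag(3), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(det(R), 1, tolerance = 1e-12)
}
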
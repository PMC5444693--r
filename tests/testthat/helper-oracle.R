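# Independent fixed-step classical RK4 integrator used as a numerical oracle
# for the adaptive solver path. It evaluates each reaction's kinetic law
# directly with eval() and assembles the stoichiometry sums itself, sharing
# no code with compile_odes()/simulate_network().
rk4_oracle <- function(net, t_end, h) {
  conc <- stats::setNames(net$species$initial_concentration, net$species$id)
  S <- matrix(0, nrow(net$species), length(net$reactions),
              dimnames = list(net$species$id, NULL))
  for (j in seq_along(net$reactions)) {
    rx <- net$reactions[[j]]
    for (s in names(rx$reactants)) S[s, j] <- S[s, j] - rx$reactants[[s]]
    for (s in names(rx$products)) S[s, j] <- S[s, j] + rx$products[[s]]
  }
  S[net$species$boundary, ] <- 0
  exprs <- lapply(net$reactions, function(rx) rx$kinetic_law)
  pl <- as.list(net$parameters)
  f <- function(t, y) {
    env <- c(as.list(y), pl, list(time = t))
    v <- vapply(exprs, eval, 0, env)
    as.numeric(S %*% v)
  }
  n <- round(t_end / h)
  out <- matrix(NA_real_, length(conc), n + 1,
                dimnames = list(names(conc), NULL))
  out[, 1] <- conc
  y <- conc
  for (i in seq_len(n)) {
    t <- (i - 1) * h
    k1 <- f(t, y); k2 <- f(t + h / 2, y + h / 2 * k1)
    k3 <- f(t + h / 2, y + h / 2 * k2); k4 <- f(t + h, y + h * k3)
    y <- stats::setNames(y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4), names(conc))
    out[, i + 1] <- y
  }
  list(time = seq(0, by = h, length.out = n + 1), conc = out)
}

# max relative deviation between a trajectory and the oracle at shared times,
# scaled per species by the oracle's max magnitude
oracle_rel_err <- function(traj, ref) {
  idx <- match(round(traj$time, 9), round(ref$time, 9))
  stopifnot(!anyNA(idx))
  scale <- pmax(apply(abs(ref$conc), 1, max), 1e-12)
  max(abs(traj$conc - ref$conc[rownames(traj$conc), idx]) / scale)
}

# 3 species pairwise connected through 3 single-substrate reactions: the
# bipartite layout graph is a symmetric hexagon
triangle_network <- function() {
  sp <- rbind(species("A", initial_concentration = 5),
              species("B", initial_concentration = 5),
              species("C", initial_concentration = 5))
  rx <- list(
    reaction("rab", c(A = 1), c(B = 1), kinetic_law = quote(k1 * A)),
    reaction("rbc", c(B = 1), c(C = 1), kinetic_law = quote(k1 * B)),
    reaction("rca", c(C = 1), c(A = 1), kinetic_law = quote(k1 * C)))
  reaction_network(sp, rx, c(k1 = 0.1), id = "triangle")
}

# structural equality of two networks (field-by-field, laws by deparse)
expect_networks_equal <- function(a, b) {
  expect_equal(a$species, b$species)
  expect_equal(names(a$parameters), names(b$parameters))
  expect_equal(unname(a$parameters), unname(b$parameters))
  expect_equal(a$compartments, b$compartments)
  expect_equal(length(a$reactions), length(b$reactions))
  for (i in seq_along(a$reactions)) {
    ra <- a$reactions[[i]]; rb <- b$reactions[[i]]
    expect_equal(ra$id, rb$id)
    expect_equal(ra$reactants, rb$reactants)
    expect_equal(ra$products, rb$products)
    expect_equal(ra$modifiers, rb$modifiers)
    expect_equal(ra$reversible, rb$reversible)
    expect_equal(deparse(ra$kinetic_law), deparse(rb$kinetic_law))
  }
}

all_motifs <- function() c("decay", "reversible_pair", "linear_cascade",
                           "receptor_inhibitor", "crosstalk_shared_phosphatase")
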
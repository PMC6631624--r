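# shared fixture builders; everything is generated in code, no files

jaccard <- function(a, b) sum(a & b) / sum(a | b)

# small scratch simulation used by several segmentation/render tests
tiny_scratch_field <- function(D = 600, tau = 20, b = 500,
                               L = 1600, n_nodes = 321,
                               t_end = 4, save_every = 2) {
  g <- grid_1d(0, L, n_nodes, t_end = t_end, save_every = save_every)
  p <- fk_parameters(D = D, tau = tau, b = b)
  list(field = simulate_fk_1d(make_scratch_initial_condition(p, g), p, g),
       params = p, grid = g)
}

# uniform-density field (fraction of u_hat) on a small grid
flat_field <- function(level, L = 1600, n_nodes = 161, u_hat = 1) {
  g <- grid_1d(0, L, n_nodes, t_end = 1, save_every = 1)
  density_field(0, matrix(level * u_hat, 1, n_nodes), g)
}

# density field whose wound (sub-threshold stripe) shrinks linearly in time:
# step profiles, half-width w0 - rate * t, for planted-area tests
linear_closing_field <- function(w0 = 400, rate = 15, times = seq(0, 20, 1),
                                 L = 1600, n_nodes = 321) {
  g <- grid_1d(0, L, n_nodes, t_end = max(times),
               save_every = if (length(times) > 1) diff(times)[1] else 1)
  vals <- t(vapply(times, function(t) {
    hw <- max(w0 - rate * t, 0)
    ifelse(abs(g$x - L / 2) <= hw, 0, 1)
  }, numeric(n_nodes)))
  density_field(times, vals, g)
}
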
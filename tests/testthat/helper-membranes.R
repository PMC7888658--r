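# shared fixtures: small membranes built in code

one_papilla_membrane <- function(R = 30, H = 60, p = 0.5, extent = c(200, 200),
                                 center = c(100, 100)) {
  membrane_model(extent, list(papilla_chart(center, build_shape_curve(R, H, p))))
}

flat_membrane <- function(extent = c(500, 500)) {
  membrane_model(extent, list())
}

# metric norm of a chart vector
metric_norm <- function(membrane, u, v) {
  sqrt(sum(v * (metric_tensor(membrane, u) %*% v)))
}

# minimal single-cell state for engine tests
single_cell_state <- function(membrane, u = NULL, nested = FALSE, p0 = 0.05) {
  if (is.null(u)) u <- membrane$extent / 2
  pos <- chart_inverse(membrane, u)
  structure(list(
    id = 1L, x = pos[1], y = pos[2], z = pos[3], u1 = u[1], u2 = u[2],
    radius = 5, generation = 0L, strain = if (nested) 1L else 0L,
    strain_generation = 0L, nested = nested, p0 = p0,
    next_id = 2L, next_strain = if (nested) 2L else 1L, time = 0
  ), class = "nevo_state")
}
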
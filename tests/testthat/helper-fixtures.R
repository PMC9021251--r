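## Shared fixtures, built once per test run and memoized. All sizes are
## deliberately coarse: the tests exercise correctness, not resolution.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

uniform_liver_table <- function(sigma0 = 0.091) {
  tissue_table(list(liver = list(cond = conductivity_fun(sigma0)),
                    electrode = list(cond = conductivity_fun(1e6))))
}

## coarse linear-pair model, nonlinear liver conductivity
fx_linear <- function() memo("linear", function() {
  lay <- place_linear_pair()
  dd <- default_domain(lay$electrodes)
  regs <- list(rect_region("liver", dd[1], dd[2], dd[3], dd[4]))
  mesh <- triangulate(regs, lay$electrodes, h_max = 0.5,
                      h_far = (dd[3] - dd[1]) / 40)
  tissues <- default_tissue_table()
  sol <- solve_pair(mesh, tissues, 1L, 2L, 2000)
  list(lay = lay, dd = dd, regs = regs, mesh = mesh, tissues = tissues,
       sol = sol)
})

## coaxial-electrode model with uniform conductivity (analytic reference)
fx_coax <- function() memo("coax", function() {
  tissues <- uniform_liver_table(0.2)
  e_in <- electrode(c(0, 0), 2, id = 1L)
  e_out <- electrode(c(0, 0), 16, id = 2L, invert = TRUE)
  regs <- list(rect_region("liver", -10, -10, 10, 10))
  mesh <- triangulate(regs, list(e_in, e_out), h_max = 0.15,
                      refinement = list(electrode = 0.075))
  sol <- solve_pair(mesh, tissues, 1L, 2L, 100)
  list(mesh = mesh, sol = sol, tissues = tissues, a = 1, b = 8, U = 100,
       sigma = 0.2)
})

## noiseless synthetic linear case on sweep-lattice thresholds
fx_case <- function() memo("case", function() {
  spec <- synthetic_case_spec("linear", thresholds_V_per_cm = c(A = 1200, B = 800),
                              px_mm = 0.1, frame_mm = 15)
  generate_case(spec, h_mm = 0.3)
})

## small hepatic-lobule lattice with one electrode pair (scaled down:
## 3.65 mm spacing so the section stays small)
fx_lattice <- function() memo("lattice", function() {
  spec <- microstructure_spec(extent_mm = c(-1.5, -2.5, 5.15, 2.5))
  regs <- build_hex_lobule_lattice(spec)
  elecs <- list(electrode(c(0, 0), 0.7, 1L), electrode(c(3.65, 0), 0.7, 2L))
  mesh <- triangulate(regs, elecs, h_max = 0.05)
  tissues <- default_tissue_table()
  list(spec = spec, regs = regs, elecs = elecs, mesh = mesh, tissues = tissues)
})

expect_rel_equal <- function(x, y, tol) {
  expect_lt(max(abs(x - y) / pmax(abs(y), 1e-300)), tol)
}
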
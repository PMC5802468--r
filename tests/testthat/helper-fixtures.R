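# Memoised fixtures shared across test files.  Everything is generated in
# code; expensive simulations are computed once per test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_env))
    assign(name, force(expr), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

san_mouse <- function() fixture("san_mouse", build_san("mouse"))
san_rabbit <- function() fixture("san_rabbit", build_san("rabbit"))
neuron <- function() fixture("neuron", build_neuron())

# 20 s unstimulated control runs (the standard pacemaking protocol)
mouse_run <- function() fixture("mouse_run",
  integrate_cell(san_mouse(), duration = 20000))
rabbit_run <- function() fixture("rabbit_run",
  integrate_cell(san_rabbit(), duration = 20000))

# control neuron f-I on the standard amplitude grid
neuron_fi <- function() fixture("neuron_fi",
  fi_curve(neuron(), amplitudes = seq(0.35, 1.4, by = 0.15),
           duration = 700))

# leak-only single-compartment cell (all active conductances zero)
leak_only_neuron <- function(g_leak = 0.02, E_leak = -70) {
  m <- build_neuron()
  for (g in c("gNaT", "gNaP", "gKdr", "gKM", "gSK", "gCaHVA", "gCaLVA",
              "gH", "gHd", "gc", "gLd"))
    m$params[[g]] <- 0
  m$params[["gLs"]] <- g_leak
  m$params[["EL"]] <- E_leak
  m$name <- "leak-only"
  m
}

# reference Ca-channel gain variant used by the tissue scenarios
tissue_ca_variant <- function() {
  variant_effect("ca-gain", "CACNA1D", list(
    parameter_modification("CaL13.gbar", "mult", 3),
    parameter_modification("CaL13.act.vhalf", "add", -8),
    parameter_modification("CaT.gbar", "mult", 3),
    parameter_modification("CaT.act.vhalf", "add", -8)))
}

# its calibrated threshold on the rabbit cell (computed once)
tissue_ca_c <- function() fixture("tissue_ca_c", {
  cs <- condition_set("san", record = 5000, settle = 1500)
  find_threshold_c(san_rabbit(), tissue_ca_variant(), cs,
                   step = 0.2, tol = 0.02)$c
})
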
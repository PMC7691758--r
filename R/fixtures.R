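# Seeded toy-project generator plus a straight-line oracle, so every module
# can be exercised end-to-end without external data.

#' Specification for a seeded toy project
#'
#' @param seed Integer RNG seed; the same seed yields byte-identical fixture
#'   files.
#' @param n_countries Number of countries.
#' @param T Horizon in periods, >= 1.
#' @param range_delta_h,range_delta_c_h,range_delta_c_c Two-element magnitude
#'   ranges (min, max) for the per-period effects.
#' @param range_g Range for the per-period growth rates (consumption,
#'   threshold).
#' @param range_k_h Range for the base threshold.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed, n_countries = 3, T = 5,
                         range_delta_h = c(-5, 20),
                         range_delta_c_h = c(-2000, 10000),
                         range_delta_c_c = c(-1000, 2000),
                         range_g = c(0, 0.05),
                         range_k_h = c(500, 5000)) {
  ranges <- list(range_delta_h = range_delta_h,
                 range_delta_c_h = range_delta_c_h,
                 range_delta_c_c = range_delta_c_c,
                 range_g = range_g, range_k_h = range_k_h)
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2L || any(!is.finite(r)) || r[1] > r[2]) {
      stop(nm, " must be a finite (min, max) pair", call. = FALSE)
    }
  }
  if (T < 1 || n_countries < 1) {
    stop("`T` and `n_countries` must be >= 1", call. = FALSE)
  }
  if (range_g[1] <= -1) stop("growth rates must be > -1", call. = FALSE)
  if (range_k_h[1] <= 0) stop("`range_k_h` must be positive", call. = FALSE)
  structure(c(list(seed = as.integer(seed), n_countries = n_countries, T = T),
              ranges),
            class = "fixture_spec")
}

# Literal per-term restatement of the appraisal: parameter values, the
# consumption-equivalent cell and its discounted contribution are rebuilt
# inside one scalar loop. Deliberately shares no arithmetic with the
# vectorised modules so it can serve as an independent check on them.
oracle_country_npv <- function(delta_h, delta_c_h, delta_c_c,
                               k_h1, k_c1, V_h1,
                               g_c, gk_h, g_kc, elasticity_V,
                               eta, delta) {
  T_ <- length(delta_h)
  r_c <- delta + eta * g_c
  npv <- 0
  for (t in seq_len(T_)) {
    k_ht <- k_h1 * (1 + gk_h)^(t - 1)
    k_ct <- k_c1 * (1 + g_kc)^(t - 1)
    V_ht <- V_h1 * (1 + elasticity_V * g_c)^(t - 1)
    net_health <- delta_h[t] - delta_c_h[t] / k_ht
    net_cons_cost <- delta_c_c[t] + k_ct * delta_c_h[t]
    eq_cons <- V_ht * net_health - net_cons_cost
    npv <- npv + eq_cons / (1 + r_c)^t
  }
  npv
}

#' Generate a seeded toy project with known answers
#'
#' Draws per-country effect streams and country parameters from the ranges in
#' the spec and writes three files into `dir`: `streams.csv` (the stream
#' schema), `contexts.yaml` (country parameters) and `expected.json`
#' (per-country and global NPVs computed by a literal per-term loop over the
#' defining formulas, independent of the package's vectorised code paths).
#' Country parameters use the conservative judgement defaults (unit
#' consumption opportunity cost, income elasticity 1, inequality aversion 1,
#' zero pure time preference) with the consumption value of health drawn
#' above the threshold.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the file `paths`, the `project`, the
#'   `contexts` and the `expected` NPVs.
#' @export
generate_fixture <- function(spec, dir = tempfile("fixture")) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$seed)
  ids <- LETTERS[seq_len(spec$n_countries)]
  if (spec$n_countries > 26) ids <- sprintf("C%02d", seq_len(spec$n_countries))
  draw <- function(range, n) stats::runif(n, range[1], range[2])

  streams <- list()
  ctx_doc <- list()
  expected <- list()
  for (id in ids) {
    s <- effect_stream(
      id,
      delta_h = draw(spec$range_delta_h, spec$T),
      delta_c_h = draw(spec$range_delta_c_h, spec$T),
      delta_c_c = draw(spec$range_delta_c_c, spec$T)
    )
    k_h1 <- draw(spec$range_k_h, 1)
    V_h1 <- k_h1 * stats::runif(1, 1.5, 4) # demand-side value above threshold
    g_c <- draw(spec$range_g, 1)
    gk_h <- draw(spec$range_g, 1)
    entry <- list(
      k_h = k_h1, V_h = V_h1, k_c = 1,
      g_c = g_c, gk_h = gk_h, g_kc = g_c, elasticity_V = 1,
      eta = 1, delta = 0, r_s = g_c, p_cat = 0,
      convention = "exact_multiplicative", currency = "INT$"
    )
    streams[[id]] <- s
    ctx_doc[[id]] <- entry
    expected[[id]] <- oracle_country_npv(
      s$delta_h, s$delta_c_h, s$delta_c_c,
      k_h1 = entry$k_h, k_c1 = entry$k_c, V_h1 = entry$V_h,
      g_c = entry$g_c, gk_h = entry$gk_h, g_kc = entry$g_kc,
      elasticity_V = entry$elasticity_V,
      eta = entry$eta, delta = entry$delta
    )
  }
  proj <- project(streams)

  paths <- list(
    streams = file.path(dir, "streams.csv"),
    contexts = file.path(dir, "contexts.yaml"),
    expected = file.path(dir, "expected.json")
  )
  write_streams(proj, paths$streams)
  yaml::write_yaml(ctx_doc, paths$contexts, precision = 17L)
  glob <- sum(unlist(expected))
  jsonlite::write_json(
    list(country_npv = expected, global_npv = glob),
    paths$expected, auto_unbox = TRUE, digits = NA
  )
  contexts <- lapply(ids, function(id) {
    e <- ctx_doc[[id]]
    country_context(
      id, k_h1 = e$k_h, V_h1 = e$V_h, k_c1 = e$k_c,
      growth = growth_spec(e$g_c, e$gk_h, e$elasticity_V, e$g_kc),
      discount = discount_spec(e$delta, e$eta, g_c = e$g_c, r_s = e$r_s,
                               p_cat = e$p_cat, convention = e$convention),
      currency = e$currency
    )
  })
  names(contexts) <- ids
  invisible(list(paths = paths, project = proj, contexts = contexts,
                 expected = list(country_npv = expected, global_npv = glob)))
}
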
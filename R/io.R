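# Readers and writers: effect-stream CSVs, country-parameter YAML/JSON,
# extensive-report rendering. CSV dialect throughout: UTF-8, comma separator,
# `.` decimal, header required; numbers are written with 17 significant
# digits so that read(write(x)) reproduces every value exactly.

fmt_num <- function(x) {
  ifelse(is.na(x), "", sprintf("%.17g", x))
}

#' Read a multi-country effect-stream CSV
#'
#' Expects columns `country,t,delta_h,delta_c_h,delta_c_c` with a header row;
#' within each country the periods `t` must run contiguously from 1 and carry
#' no duplicates. Parse errors name the offending file line.
#'
#' @param path Path to the CSV file.
#' @param health_metric Health metric label applied to all streams.
#' @return A [project()] with one [effect_stream()] per country.
#' @export
load_streams <- function(path, health_metric = "QALY_gained") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("country", "t", "delta_h", "delta_c_h", "delta_c_c")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("stream CSV is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  streams <- lapply(split(seq_len(nrow(df)), df$country), function(rows) {
    sub <- df[rows, ]
    ord <- order(sub$t)
    sub <- sub[ord, ]
    rows <- rows[ord]
    country <- sub$country[1L]
    if (anyDuplicated(sub$t)) {
      dup <- sub$t[duplicated(sub$t)][1L]
      line <- rows[sub$t == dup][2L] + 1L
      stop(sprintf("duplicate (country, t) = (%s, %d) at line %d",
                   country, dup, line), call. = FALSE)
    }
    if (!identical(as.integer(sub$t), seq_len(nrow(sub)))) {
      bad <- which(as.integer(sub$t) != seq_len(nrow(sub)))[1L]
      stop(sprintf(
        "periods for country %s are not contiguous from 1 (line %d has t = %s)",
        country, rows[bad] + 1L, sub$t[bad]), call. = FALSE)
    }
    effect_stream(country, sub$delta_h, sub$delta_c_h, sub$delta_c_c,
                  health_metric = health_metric)
  })
  project(streams)
}

#' Write a project to the effect-stream CSV schema
#'
#' @param proj A [project()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_streams <- function(proj, path) {
  stopifnot(inherits(proj, "project"))
  rows <- lapply(proj, function(s) {
    data.frame(country = s$country_id, t = seq_len(s$T),
               delta_h = fmt_num(s$delta_h),
               delta_c_h = fmt_num(s$delta_c_h),
               delta_c_c = fmt_num(s$delta_c_c),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

context_keys <- c(
  "k_h", "V_h", "k_c", "g_c", "gk_h", "g_kc", "elasticity_V", "eta",
  "delta", "r_s", "p_cat", "beta_premium", "convention", "currency",
  "scenarios", "shadow_ratio_x", "profile"
)

#' Read country contexts from YAML or JSON
#'
#' The document maps country ids to parameter entries (optionally nested
#' under a top-level `countries` key). Each entry gives base parameter values
#' and growth/discounting fields; omitted judgement parameters are filled
#' from a named defaults profile (conservative unless the entry names
#' another), and every applied default is logged via `message()` so reports
#' can trace each parameter to user input or a named default.
#'
#' Recognised keys per country: `k_h`, `V_h` (required bases), `k_c`, `g_c`
#' (required unless `scenarios` given), `gk_h`, `g_kc`, `elasticity_V`,
#' `eta`, `delta`, `r_s`, `p_cat`, `beta_premium`, `convention`, `currency`,
#' `scenarios` (list of `{g, p}`), `shadow_ratio_x`, `profile`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @param quiet Suppress the default-fill log messages.
#' @return Named list of [country_context()] objects.
#' @export
load_contexts <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  doc <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyVector = FALSE),
    stop("unsupported context file extension: .", ext, call. = FALSE)
  )
  if (!is.null(doc$countries)) doc <- doc$countries
  if (is.null(names(doc)) || any(names(doc) == "")) {
    stop("context document must map country ids to parameter entries",
         call. = FALSE)
  }
  contexts <- lapply(names(doc), function(id) {
    entry <- doc[[id]]
    unknown <- setdiff(names(entry), context_keys)
    if (length(unknown) > 0) {
      stop(sprintf("unknown key(s) for country %s: %s", id,
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
    profile <- defaults_profile(entry$profile %||% "conservative")
    log_default <- function(key, value) {
      if (!quiet) {
        message(sprintf("INFO [%s] default applied: %s = %s (%s profile)",
                        id, key, format(value), profile$profile))
      }
      value
    }
    pick <- function(key) {
      if (is.null(entry[[key]])) log_default(key, profile[[key]])
      else entry[[key]]
    }
    if (is.null(entry$k_h)) {
      stop(sprintf("country %s: base threshold `k_h` is required", id),
           call. = FALSE)
    }
    if (is.null(entry$V_h)) {
      stop(sprintf("country %s: base consumption value `V_h` is required", id),
           call. = FALSE)
    }
    if (is.null(entry$g_c) && is.null(entry$scenarios)) {
      stop(sprintf(
        "country %s: consumption growth `g_c` or `scenarios` is required", id),
        call. = FALSE)
    }
    if (!is.finite(entry$k_h) || entry$k_h <= 0) {
      stop(sprintf("country %s: `k_h` must be > 0", id), call. = FALSE)
    }
    scen <- entry$scenarios
    if (!is.null(scen)) {
      scen <- do.call(rbind, lapply(scen, function(s) {
        data.frame(g = s$g, p = s$p)
      }))
    }
    g_c_point <- entry$g_c %||%
      if (!is.null(scen)) sum(scen$g * scen$p) else NULL
    g_kc <- entry$g_kc
    if (is.null(g_kc)) {
      # default: consumption opportunity costs grow with consumption
      g_kc <- log_default("g_kc", g_c_point)
    }
    growth <- growth_spec(
      g_c = g_c_point,
      gk_h = if (is.null(entry$gk_h)) log_default("gk_h", 0) else entry$gk_h,
      elasticity_V = pick("elasticity_V"),
      g_kc = g_kc
    )
    discount <- discount_spec(
      delta = pick("delta"),
      eta = pick("eta"),
      g_c = entry$g_c,
      scenarios = scen,
      r_s = entry$r_s,
      p_cat = pick("p_cat"),
      beta_premium = entry$beta_premium %||% 0,
      convention = entry$convention %||% "exact_multiplicative"
    )
    country_context(
      id = id, k_h1 = entry$k_h, V_h1 = entry$V_h, k_c1 = pick("k_c"),
      growth = growth, discount = discount,
      shadow_ratio_x = entry$shadow_ratio_x,
      currency = entry$currency %||% "INT$"
    )
  })
  names(contexts) <- names(doc)
  contexts
}

#' Render an appraisal as an extensive report
#'
#' `format = "csv"` writes the extensive table wide (one row per period, all
#' columns, 17 significant digits) followed by an `NPV` row carrying the
#' country NPV in the `eq_consumption` column; [read_extensive_csv()] parses
#' it back exactly. `format = "text"` prints aligned blocks mirroring the
#' three reporting tables (health effects, health/consumption net effects,
#' per-numeraire net effects) plus the NPV block and the conventions used.
#'
#' @param result An [npv_country()] result.
#' @param format `"text"` or `"csv"`.
#' @param file Optional output path; when `NULL` the document is returned as
#'   a character vector (and printed for `"text"`).
#' @return The document lines, invisibly when written to `file`.
#' @export
render_extensive_report <- function(result, format = c("text", "csv"),
                                    file = NULL) {
  stopifnot(inherits(result, "appraisal_result"))
  format <- match.arg(format)
  tbl <- result$table
  if (format == "csv") {
    num_cols <- setdiff(names(tbl), "t")
    out <- data.frame(t = as.character(tbl$t), stringsAsFactors = FALSE)
    for (cc in num_cols) out[[cc]] <- fmt_num(tbl[[cc]])
    npv_row <- as.list(rep("", ncol(out)))
    names(npv_row) <- names(out)
    npv_row$t <- "NPV"
    npv_row$eq_consumption <- fmt_num(result$npv)
    out <- rbind(out, as.data.frame(npv_row, stringsAsFactors = FALSE))
    lines <- c(paste(names(out), collapse = ","),
               apply(out, 1L, paste, collapse = ","))
  } else {
    f <- function(x) format(x, digits = 6, trim = TRUE)
    block <- function(title, df) {
      c(title, utils::capture.output(print.data.frame(df, row.names = FALSE)))
    }
    lines <- c(
      sprintf("Extensive report: country %s (%s)", result$country_id,
              result$currency),
      sprintf("Convention: %s; accrual: %s", result$convention,
              result$accrual),
      "",
      block("-- Effects and health representation --", data.frame(
        t = tbl$t, delta_h = f(tbl$delta_h), delta_c_h = f(tbl$delta_c_h),
        health_gained = f(tbl$health_gained),
        health_loss = f(tbl$health_loss),
        resource_benefit = f(tbl$resource_benefit),
        resource_cost = f(tbl$resource_cost),
        cons_value_gained = f(tbl$consumption_value_gained),
        cons_value_lost = f(tbl$consumption_value_lost)
      )),
      "",
      block("-- Net health and net consumption --", data.frame(
        t = tbl$t, delta_h = f(tbl$delta_h), delta_c_h = f(tbl$delta_c_h),
        delta_c_c = f(tbl$delta_c_c),
        net_health_benefit = f(tbl$net_health_benefit),
        net_consumption_cost = f(tbl$net_consumption_cost)
      )),
      "",
      block("-- Net effects per numeraire --", data.frame(
        t = tbl$t, eq_consumption = f(tbl$eq_consumption),
        eq_health = f(tbl$eq_health), eq_resource = f(tbl$eq_resource)
      )),
      "",
      sprintf("Net present value (consumption numeraire): %s %s",
              f(result$npv), result$currency)
    )
    if (!is.null(result$icer)) {
      lines <- c(lines, sprintf(
        "ICER (reported alongside, dual rates %s): %s vs k_h1 = %s [%s] -> %s",
        result$icer$convention, f(result$icer$icer), f(result$icer$k_h1),
        result$icer$quadrant, result$icer$verdict))
    }
  }
  if (is.null(file)) {
    if (format == "text") {
      cat(lines, sep = "\n")
      return(invisible(lines))
    }
    return(lines)
  }
  writeLines(lines, file)
  invisible(lines)
}

#' Parse an extensive-report CSV back into its numbers
#'
#' @param path Path written by [render_extensive_report()] with
#'   `format = "csv"`.
#' @return A list with `table` (tibble of per-period columns) and `npv`.
#' @export
read_extensive_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  npv_row <- df$t == "NPV"
  npv <- as.numeric(df$eq_consumption[npv_row])
  body <- df[!npv_row, ]
  tbl <- tibble::as_tibble(lapply(body, as.numeric))
  list(table = tbl, npv = npv)
}
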
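# Internal ILP backend. Domination problems are 0/1 covering programs:
#   minimize sum_i c_i x_i  s.t.  sum_{j in S_r} x_j >= 1 for each row r,
# with optional forced variables (x_i = 1) and an optional cardinality pin
# (sum_i x_i == s) used by the canonical second-stage solve.
# Solved with the GLPK stand-alone solver via CPLEX-LP files.

glpsol_path <- function() {
  p <- Sys.which("glpsol")
  if (!nzchar(p)) {
    abort("The GLPK solver 'glpsol' was not found on the PATH.",
          class = "multidom_solver_error")
  }
  p
}

# rows: list of integer vectors of variable indices (all coefficients 1)
glpk_solve_cover <- function(n_var, rows, obj = NULL, forced = integer(),
                             pin_size = NULL, time_limit = 600) {
  if (n_var == 0L) {
    return(list(status = "optimal", x = integer(0), objective = 0))
  }
  obj <- obj %||% rep(1, n_var)
  x <- integer(n_var)
  x[forced] <- 1L
  if (length(rows) == 0L && is.null(pin_size)) {
    # nothing to cover: forced variables alone are optimal
    return(list(status = "optimal", x = x, objective = sum(obj * x)))
  }

  lp <- tempfile(fileext = ".lp")
  sol <- tempfile(fileext = ".sol")
  on.exit(unlink(c(lp, sol)), add = TRUE)

  obj_terms <- paste0(format(obj, scientific = FALSE, trim = TRUE), " x", seq_len(n_var))
  # objective wrapped over several lines to keep LP-format records short
  lines <- c("Minimize",
             paste0(" obj: ", paste(obj_terms[seq_len(min(12L, n_var))], collapse = " + ")))
  if (n_var > 12L) {
    rest <- split(obj_terms[-seq_len(12L)], ceiling(seq_along(obj_terms[-seq_len(12L)]) / 12))
    lines <- c(lines, vapply(rest, function(ch) paste0("  + ", paste(ch, collapse = " + ")), ""))
  }
  lines <- c(lines, "Subject To")
  if (length(rows) > 0L) {
    lines <- c(lines, vapply(seq_along(rows), function(r) {
      paste0(" c", r, ": ", paste0("x", rows[[r]], collapse = " + "), " >= 1")
    }, ""))
  }
  if (!is.null(pin_size)) {
    vs <- paste0("x", seq_len(n_var))
    chunks <- split(vs, ceiling(seq_len(n_var) / 12))
    body <- paste0(" card: ", paste(chunks[[1]], collapse = " + "))
    if (length(chunks) > 1L) {
      body <- c(body, vapply(chunks[-1], function(ch) paste0("  + ", paste(ch, collapse = " + ")), ""))
    }
    body[length(body)] <- paste0(body[length(body)], " = ", pin_size)
    lines <- c(lines, body)
  }
  if (length(forced) > 0L) {
    lines <- c(lines, "Bounds", paste0(" x", forced, " >= 1"))
  }
  vs <- paste0("x", seq_len(n_var))
  lines <- c(lines, "Binary",
             vapply(split(vs, ceiling(seq_len(n_var) / 20)),
                    function(ch) paste0(" ", paste(ch, collapse = " ")), ""),
             "End")
  writeLines(lines, lp)

  code <- system2(glpsol_path(),
                  c("--lp", shQuote(lp), "--tmlim", format(ceiling(time_limit)),
                    "-o", shQuote(sol)),
                  stdout = FALSE, stderr = FALSE)
  if (code != 0L || !file.exists(sol)) {
    abort(sprintf("glpsol failed with exit code %d", code),
          class = "multidom_solver_error", status = "failed")
  }
  out <- readLines(sol, warn = FALSE)
  status_line <- grep("^Status:", out, value = TRUE)
  status_raw <- if (length(status_line)) trimws(sub("^Status:", "", status_line[[1]])) else ""
  status <- if (grepl("INTEGER OPTIMAL", status_raw)) {
    "optimal"
  } else if (grepl("EMPTY|NO .*FEASIBLE|INFEASIBLE", status_raw)) {
    "infeasible"
  } else {
    "timeout"
  }
  x <- integer(n_var)
  if (status == "optimal") {
    m <- regmatches(out, regexec("^\\s*\\d+\\s+x(\\d+)\\s+\\*?\\s+([01])\\b", out))
    hits <- m[vapply(m, length, 1L) == 3L]
    for (h in hits) x[as.integer(h[[2]])] <- as.integer(h[[3]])
  }
  list(status = status, x = x, objective = sum(obj * x))
}
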
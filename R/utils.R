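# internal validation helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_pv <- function(..., class = "pvgrad_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_same_shape <- function(..., what = "arrays") {
  arrs <- list(...)
  dims <- lapply(arrs, dim)
  ref <- dims[[1]]
  for (d in dims[-1]) {
    if (!identical(ref, d)) {
      stop_pv(what, " must share one grid: found dims ",
              paste(ref, collapse = "x"), " vs ", paste(d, collapse = "x"),
              class = "pvgrad_shape_error")
    }
  }
  invisible(TRUE)
}

check_binary <- function(mask, name) {
  u <- unique(as.vector(mask))
  u <- u[!is.na(u)]
  if (!all(u %in% c(0, 1, TRUE, FALSE))) {
    stop_pv(name, " is not binary: values ",
            paste(head(sort(u), 5), collapse = ", "),
            class = "pvgrad_binarity_error")
  }
  invisible(TRUE)
}

# Deterministic per-unit child seed from a root seed, so that adding a
# subject/stream never perturbs the draws of another. Kept < 2^31.
child_seed <- function(root_seed, index) {
  (as.double(root_seed) * 48271 + as.double(index) * 6007) %% 2147483647
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
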
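# Run code with a temporary RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stop_thz <- function(msg, class) {
  abort(msg, class = c(class, "thz_error"))
}

# wavenumber (rad/um) at frequency f (THz)
wavenumber <- function(f_thz) 2 * pi * f_thz / .c_um_thz

deg2rad <- function(deg) deg * pi / 180

is_uniform <- function(x, rtol = 1e-9) {
  if (length(x) < 2L) return(TRUE)
  d <- diff(x)
  step <- d[1L]
  step > 0 && max(abs(d - step)) < rtol * abs(step)
}
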
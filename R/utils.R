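# internal helpers shared across modules

# round half away from zero, matching the printed style of clinical tables
# (base round() rounds half to even)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# hospitalization week: days 1-7 are week 1
week_of_day <- function(day) as.integer(ceiling(day / 7))
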
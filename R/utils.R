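# Internal helpers: classed conditions and number formatting.

stop_deltabeta <- function(subclass, msg, ...) {
  stop(structure(
    class = c(paste0("deltabeta_", subclass), "deltabeta_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

#' @importFrom stats plogis qlogis
logit <- function(p) qlogis(p)
inv_logit <- function(x) plogis(x)

# Shortest decimal rendering that re-reads to the same double. 15 significant
# digits round-trips almost everything; fall back to 17 where it does not.
fmt_num <- function(x) {
  out <- character(length(x))
  out[is.na(x)] <- "NA"
  ok <- !is.na(x)
  s <- formatC(x[ok], digits = 15, format = "g")
  bad <- as.numeric(s) != x[ok]
  s[bad] <- formatC(x[ok][bad], digits = 17, format = "g")
  out[ok] <- s
  out
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)
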
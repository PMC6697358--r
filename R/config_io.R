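# Plain-text (INI-style) serialization of network configurations.
# Numbers are written with 17 significant digits so a write/read
# round trip is bit-exact.

fmt_num <- function(x) sprintf("%.17g", x)

#' Write a configuration to a text file
#'
#' Key-value format with `[shared]`, `[unit <i>]`, `[weights]` and
#' `[drives]` sections. Round-trips exactly through
#' [read_cpg_config()].
#'
#' @param config a [network_config()]
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_cpg_config <- function(config, path) {
  n <- length(config$units)
  ln <- c("[network]",
          paste("n_units =", n),
          paste("h_mode =", config$h_mode),
          "", "[shared]")
  s <- config$shared
  for (k in names(unclass(s))) ln <- c(ln, paste(k, "=", fmt_num(s[[k]])))
  for (i in seq_len(n)) {
    u <- config$units[[i]]
    ln <- c(ln, "", paste0("[unit ", i, "]"),
            paste("name =", u$name),
            paste("excitatory =", u$excitatory))
    for (k in c("g_NaP", "g_K", "g_L", "E_L", "theta_out", "sigma_out"))
      ln <- c(ln, paste(k, "=", fmt_num(u[[k]])))
    if (!u$excitatory)
      for (k in c("tau_p", "d_adapt"))
        ln <- c(ln, paste(k, "=", fmt_num(u[[k]])))
    if (u$inh0 != 0) ln <- c(ln, paste("inh0 =", fmt_num(u$inh0)))
  }
  ln <- c(ln, "", "[weights]")
  for (j in seq_len(n)) for (i in seq_len(n)) {
    if (config$a[j, i] != 0)
      ln <- c(ln, paste0("a", j, i, " = ", fmt_num(config$a[j, i])))
    if (config$b[j, i] != 0)
      ln <- c(ln, paste0("b", j, i, " = ", fmt_num(config$b[j, i])))
  }
  ln <- c(ln, "", "[drives]",
          paste("c1 =", paste(fmt_num(config$c1), collapse = " ")),
          paste("c2 =", paste(fmt_num(config$c2), collapse = " ")))
  writeLines(ln, path)
  invisible(path)
}

#' Read a configuration from a text file
#'
#' @param path file written by [write_cpg_config()]
#' @return a [network_config()]
#' @export
read_cpg_config <- function(path) {
  ln <- trimws(readLines(path))
  ln <- ln[nzchar(ln)]
  section <- ""
  kv <- list()
  for (l in ln) {
    if (grepl("^\\[", l)) {
      section <- gsub("^\\[|\\]$", "", l)
      kv[[section]] <- list()
    } else {
      p <- strsplit(l, "=", fixed = TRUE)[[1]]
      if (length(p) != 2) stop("malformed line: ", l)
      kv[[section]][[trimws(p[1])]] <- trimws(p[2])
    }
  }
  n <- as.integer(kv$network$n_units)
  sh <- do.call(shared_params, lapply(kv$shared, as.numeric))
  units <- lapply(seq_len(n), function(i) {
    u <- kv[[paste0("unit ", i)]]
    exc <- as.logical(u$excitatory)
    unit_params(u$name, exc,
                g_NaP = as.numeric(u$g_NaP), g_K = as.numeric(u$g_K),
                g_L = as.numeric(u$g_L), E_L = as.numeric(u$E_L),
                theta_out = as.numeric(u$theta_out),
                sigma_out = as.numeric(u$sigma_out),
                tau_p = if (exc) NA_real_ else as.numeric(u$tau_p),
                d_adapt = if (exc) NA_real_ else as.numeric(u$d_adapt),
                inh0 = if (is.null(u$inh0)) 0 else as.numeric(u$inh0))
  })
  a <- matrix(0, n, n); b <- matrix(0, n, n)
  for (k in names(kv$weights)) {
    j <- as.integer(substr(k, 2, 2)); i <- as.integer(substr(k, 3, 3))
    w <- as.numeric(kv$weights[[k]])
    if (startsWith(k, "a")) a[j, i] <- w else b[j, i] <- w
  }
  c1 <- as.numeric(strsplit(kv$drives$c1, " +")[[1]])
  c2 <- as.numeric(strsplit(kv$drives$c2, " +")[[1]])
  network_config(units, sh, a, b, c1, c2, h_mode = kv$network$h_mode)
}

#' Export a trace to a delimited table
#'
#' One row per sample (t plus per-unit V, h, p, f_out, inh_sum),
#' tab-separated with a header naming the units.
#' @param trace a `cpg_trace`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_trace <- function(trace, path) {
  utils::write.table(as.data.frame(trace), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
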
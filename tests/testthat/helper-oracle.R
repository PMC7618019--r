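# Independent, naive (loop-per-photon) slab Monte Carlo used as an oracle
# for the compiled transport kernel. Deliberately textbook-style and
# structurally different from the kernel: R's own RNG, stochastic
# reflect-or-escape boundary decisions (no partial-transmission splitting),
# plain roulette without conservation bookkeeping.
naive_mc_slab <- function(mu_a, mu_s, g, n_photons, thickness = 3,
                          n_in = 1.44, n_out = 1.0, seed = 1,
                          w_min = 1e-4, p_surv = 0.1) {
  set.seed(seed)
  mu_t <- mu_a + mu_s
  r_sp <- ((n_in - n_out) / (n_in + n_out))^2
  fresnel <- function(ci) {
    if (n_in == n_out) return(0)
    si <- sqrt(1 - ci^2)
    st <- si * n_in / n_out
    if (st >= 1) return(1)
    ct <- sqrt(1 - st^2)
    rs <- (n_in * ci - n_out * ct) / (n_in * ci + n_out * ct)
    rp <- (n_in * ct - n_out * ci) / (n_in * ct + n_out * ci)
    (rs^2 + rp^2) / 2
  }
  escaped <- numeric(n_photons)
  for (ip in seq_len(n_photons)) {
    z <- 0; u <- c(0, 0, 1); w <- 1 - r_sp
    esc <- 0
    repeat {
      s <- -log(runif(1)) / mu_t
      # walk, resolving boundary hits stochastically
      repeat {
        db <- if (u[3] > 0) (thickness - z) / u[3]
              else if (u[3] < 0) -z / u[3] else Inf
        if (db <= s) {
          z <- z + db * u[3]
          s <- s - db
          rf <- fresnel(abs(u[3]))
          if (runif(1) > rf) {            # escapes entirely
            if (u[3] < 0) esc <- esc + w
            w <- 0
            break
          }
          u[3] <- -u[3]
          z <- if (u[3] > 0) 0 else thickness
        } else {
          z <- z + s * u[3]
          break
        }
      }
      if (w == 0) break
      w <- w * mu_s / mu_t                 # implicit absorption
      if (w == 0) break
      ct <- if (g == 0) 2 * runif(1) - 1 else {
        tmp <- (1 - g^2) / (1 - g + 2 * g * runif(1))
        max(-1, min(1, (1 + g^2 - tmp^2) / (2 * g)))
      }
      st <- sqrt(1 - ct^2)
      phi <- 2 * pi * runif(1)
      if (abs(u[3]) > 0.99999) {
        u <- c(st * cos(phi), st * sin(phi), sign(u[3]) * ct)
      } else {
        dn <- sqrt(1 - u[3]^2)
        u <- c(st * (u[1] * u[3] * cos(phi) - u[2] * sin(phi)) / dn + u[1] * ct,
               st * (u[2] * u[3] * cos(phi) + u[1] * sin(phi)) / dn + u[2] * ct,
               -st * cos(phi) * dn + u[3] * ct)
        u <- u / sqrt(sum(u^2))
      }
      if (w < w_min) {
        if (runif(1) < p_surv) w <- w / p_surv else break
      }
    }
    escaped[ip] <- esc
  }
  list(r_diffuse = mean(escaped),
       se = stats::sd(escaped) / sqrt(n_photons))
}
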
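# Independent studentized-range CDF by direct numerical integration
# (nested quadrature over the range statistic and the pooled-SD scale),
# used as the oracle for Tukey HSD adjusted p-values.
oracle_ptukey <- function(q, k, df) {
  inner <- function(s) {
    # P(range of k std normals <= q * s)
    f <- function(z)
      stats::dnorm(z) * (stats::pnorm(z) - stats::pnorm(z - q * s))^(k - 1)
    k * stats::integrate(f, -Inf, Inf, rel.tol = 1e-10)$value
  }
  # density of s = sqrt(chi2_df / df)
  dens <- function(s)
    2 * (df / 2)^(df / 2) / gamma(df / 2) * s^(df - 1) * exp(-df * s^2 / 2)
  f_outer <- function(s) vapply(s, function(si) dens(si) * inner(si),
                                numeric(1))
  stats::integrate(f_outer, 0, Inf, rel.tol = 1e-9)$value
}
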
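#!/usr/bin/env python
"""Generate exact Stevens-operator matrices with sympy as an oracle fixture.

Expands the extended Stevens operators O_k^q (k = 2, 4, 6; even q) from the
ladder algebra in exact arithmetic, for every spin S <= 4 where the order is
admissible (k <= 2S).  Basis order is m = +S ... -S.  Output is a TSV of the
nonzero elements, evaluated to 17 significant digits, consumed by
tests/testthat/test-spin-ops.R.
"""
import sympy as sp

def ladder(S):
    dim = int(2 * S + 1)
    ms = [S - i for i in range(dim)]          # descending m
    Sz = sp.zeros(dim, dim)
    Sp = sp.zeros(dim, dim)
    for j, m in enumerate(ms):
        Sz[j, j] = m
        if j >= 1:                            # |m> -> |m+1> sits one row up
            Sp[j - 1, j] = sp.sqrt(S * (S + 1) - m * (m + 1))
    return Sz, Sp, Sp.T

def stevens(S, k, q):
    Sz, Sp, Sm = ladder(S)
    X = S * (S + 1)
    I = sp.eye(Sz.shape[0])
    A2 = Sp**2 + Sm**2
    A4 = Sp**4 + Sm**4
    A6 = Sp**6 + Sm**6
    if (k, q) == (2, 0):
        return 3 * Sz**2 - X * I
    if (k, q) == (2, 2):
        return A2 / 2
    if (k, q) == (4, 0):
        return 35 * Sz**4 - (30 * X - 25) * Sz**2 + (3 * X**2 - 6 * X) * I
    if (k, q) == (4, 2):
        P = 7 * Sz**2 - (X + 5) * I
        return (P * A2 + A2 * P) / 4
    if (k, q) == (4, 4):
        return A4 / 2
    if (k, q) == (6, 0):
        return (231 * Sz**6 - (315 * X - 735) * Sz**4
                + (105 * X**2 - 525 * X + 294) * Sz**2
                + (-5 * X**3 + 40 * X**2 - 60 * X) * I)
    if (k, q) == (6, 2):
        P = 33 * Sz**4 - (18 * X + 123) * Sz**2 + (X**2 + 10 * X + 102) * I
        return (P * A2 + A2 * P) / 4
    if (k, q) == (6, 4):
        P = 11 * Sz**2 - (X + 38) * I
        return (P * A4 + A4 * P) / 4
    if (k, q) == (6, 6):
        return A6 / 2
    raise ValueError((k, q))

def main():
    combos = [(2, 0), (2, 2), (4, 0), (4, 2), (4, 4),
              (6, 0), (6, 2), (6, 4), (6, 6)]
    lines = ["twoS\tk\tq\trow\tcol\tvalue"]
    for twoS in range(2, 9):                  # S = 1 ... 4
        S = sp.Rational(twoS, 2)
        for (k, q) in combos:
            if k > twoS:
                continue
            O = sp.expand(stevens(S, k, q))
            dim = int(2 * S + 1)
            for i in range(dim):
                for j in range(dim):
                    v = sp.nsimplify(O[i, j])
                    if v != 0:
                        lines.append("%d\t%d\t%d\t%d\t%d\t%.17g"
                                     % (twoS, k, q, i + 1, j + 1,
                                        float(sp.N(v, 25))))
    with open("tests/testthat/fixtures/stevens-oracle.tsv", "w") as fh:
        fh.write("\n".join(lines) + "\n")
    print("wrote", len(lines) - 1, "elements")

if __name__ == "__main__":
    main()
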
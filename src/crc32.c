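/* CRC-32 of a raw vector via zlib (ZIP member checksums). */
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <zlib.h>

static SEXP C_crc32(SEXP bytes)
{
    uLong crc = crc32(0L, Z_NULL, 0);
    crc = crc32(crc, RAW(bytes), (uInt) XLENGTH(bytes));
    return ScalarReal((double) crc);
}

static const R_CallMethodDef callMethods[] = {
    {"C_crc32", (DL_FUNC) &C_crc32, 1},
    {NULL, NULL, 0}
};

void R_init_provreplay(DllInfo *info)
{
    R_registerRoutines(info, NULL, callMethods, NULL, NULL);
    R_useDynamicSymbols(info, FALSE);
    R_forceSymbols(info, TRUE);
}
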
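term,snomed_code
ABDOMEN UEBERSICHT,818983003
BAUCH,818983003
ABD,818983003
OBERARM,120574008
HUMERUS,120574008
ARM,120574008
HANDGELENK,8205005
HAND LINKS AUFNAHME,85562004
MANUS,85562004
ELLENBOGEN,127949000
ELLBOGEN,127949000
CARPUS,8205005
DIG,7569003
FINGER II,7569003
DAUMEN GRUNDGELENK,76505004
POLLEX,76505004
AC GELENK,85856004
SCHULTERECKGELENK,85856004
SCHULTER,16982005
UNTERARM MIT HANDGELENK,14975008
RADIUS ULNA,14975008
BECKEN,12921003
BECKENUEBERSICHT,12921003
OBERSCHENKEL,302524008
FEMUR,302524008
KNIE,72696002
KNIEGELENK,72696002
GENU,72696002
FUSS,56459004
PES,56459004
VORFUSS,56459004
HUEFTE,29836001
HUEFTGELENK,29836001
COXA,29836001
ZEHE,29707007
GROSSZEHE,29707007
SPRUNGGELENK,344001
OSG,344001
KNIESCHEIBE,64234005
UNTERSCHENKEL,120575009
BEIN,120575009
TIBIA FIBULA,120575009
MAMMA,76752008
MAMMOGRAPHIE,76752008
SCHAEDEL,89546000
HEAD,89546000
SKULL,89546000
KALOTTE,89546000
NASENBEIN,45206002
NASE,45206002
UNTERKIEFER,91609006
KIEFER,91609006
MANDIBULA,91609006
THORAX,51185008
BRUSTKORB,51185008
THORAX LIEGEND,51185008
RIPPEN,113197003
RIPPE,113197003
HWS,122494005
HALSWIRBELSAEULE,122494005
LWS,122496007
LENDENWIRBELSAEULE,122496007
TH LWS UEBERGANG,264232007
THORAKOLUMBAL,264232007
BWS,122495006
BRUSTWIRBELSAEULE,122495006
WIRBELSAEULE,51282000
WS GANZAUFNAHME,51282000
CLAVICULA,51299004
SCHLUESSELBEIN,51299004
SAKRUM,54735007
OS SACRUM,54735007
BRUSTBEIN,56873002
STERNUM SEITLICH,56873002
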
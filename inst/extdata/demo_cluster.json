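{"cluster_id":"demo_sulfazecin_like","genes":[{"gene_id":"nrps1","sequence":"GMGFVSELAQDVHTSKLKNQKFNQECTANFIDSEMPFVNAIKGMNFWKRTNISSKGSAAPLDYAMSGLLTNVVFQNFPEGHGKFEGMLENGRYELAEYMQRTATPGLGMIERKFRGIQGLVQPFYAYKNWPIEFCTGHQEDIEGDDRVATAQGISRKQWVVWDRSCPQLGFRILGTTGSAQSLIPEEILGITLKIDIETRVAFEYHLRDYETERLVACEAIHNKHKDERVSEYKILLTYLLYVFSKGIHLIQACLQILVILFVSMTRDWRTRVFTDVGKDYRNHGQMEGCNICANILSLARCETAWVPFMVRDSIVTVERGGEWINLLTMEEEEETFEDSLLALKKKEGYQHQMEISGAENPKNDYVDAFLLFLAGHLASCMINGTEKITMLPPNMKDTQTVPGVHDPQPLDPGLRNWHASGWGVSQRAGVVTGAVLKADDENLAAPGMQMATCYHNETKGSKSLYALGQKMSGFARANKSQIRMIELKEGFTLTGRTDTSMADKAISGAEKEEINISNLYIVSMAAYINGRHTHQVSLIFDIVMSGQDARGISHVPSASLNFMPAGKMVAADDNMFITKALSQEIELAAKGGFEAIRGFNARVPGAYRRLILASFKFVKLIKDDTAFSFQYLAGLLDYIACEATLDAEGRYFNFNQTLALVKDELPPISGGAVRNVVPHGRKIVIRQMYSHCFGAVEVEGFFTGELEKESKAAEQYFNGTADLGVNLAHEPQANAKSEPYRLKARMSSDAMHRKAKEETDSFRTSVIMVQLSNRDLVDGRVIPMHLIATRKCATISPVADPILAKNIADSEQAKYRELKKDGHADIATLPISDYRMSEFIYGVIIFPETVRTPFFLTMHTTRQFATGLTTPRVAGDLRINFLNETEKTHKVYKPKVALQPLAGWTPYELEFSLSLLPEPSPQQTGVPLASHFYGVVEAVAKSVKNQDYGTLDLDSKEIPYHKVPLINGWAPCTPISIADLIKSEAPFAFLKANEPFRITQINLRWGLSNDPEMHKVLMNRVFGPKMLRIEASCEPQRDVWRPPYAHNAFAKMEQNCINKDQNPYVTKLSNSREIQGIGSIFDYECEFHDSDEHVGDKVDVLTGAESPSQALVNYADELTEGTIKSIAGRFLYGQELDEVSPQVWDLTLSEIIRYKASLVALKKGHKEHQLNKGYSIVPEQLIKEGAMLARSLQILVGPSVATDQEAAEPNYKLFRQTLEDCVQGPLCEEETSSDEYEVLEVCLERATYMLTLNMVKGAISEFGNAYEVPFTKVNALVRAVPSDPILEGNVMLGGCNEKEQASFNMLEAVFEAIKRGEMGYVYHVTEVLHLAGAVSTDMKTRLTKRKDILESAFLRRTSAINDAQILVSVHEAFDRIFTSLYSTCLELSASLVNVKTGALHGRQNFLQDNIDPEEVFTCAGDSNYLLLGIRTQLVSAVKITIAPVIFEPLLLNSRGGSKIGEEPNNEDQILPKENVMERILDDTHILASQKFAQELMMNQHLRLKQVYYLQQKQGITAYDLWEKFINSAASMITVGANPALLVFTPLKGRFIGMKSVSRLQLLGWTAELAYIAWTYCYGTQGPYGETVHIGFLDIQLLSTEVLDMVPTSVAQTACGVDGRAKPIALHARTCGDEDEGDVFTGVGYPCYPIDKMLQVVTIKASTICVAVEKKGATAERLLCKGRPPPKHCAVKPKILLAVAYRIHTRSASIHTTGLMALDIAHAYHASPFHDSIAFIIIEEPRYMATQRKQFDAIYLETTLVYKGADQYTQEYLLHSGPGLGIGLKGCREQRLEKDTYDPFFEKLRSEPSTIIHCGFQVIMVLAPRGYRRAEPPEMISGFGLMSVGMLFDQGLNNAVPCNEPDGPDDDAYAFSEEQMRMLPSVSKPNNMNRIVNNLAKKSFGGEIDIDASIVIKETSASNIQFVEAFAGSEEPGAAQPLVDRSNFQMIAETNDVDDLFIHGKNNVDIKTESLRTIETILIKDHDVTKYFLVSAQGATHVLEDGNLQKDVKKKEANLRTRRVRILLLINTSPRREHLKGNVAAEANYDGISGLEEPTRTLKFRLYAMLYLNFGHRFLSTFGNETKCQLSKASRPRQGSAKCDLEIPDKLTEIAYDFSFVIFVATDSQANATRKMRCVEAYPLRVLKRTGVQWWREISGRPSELRLPLPKPEPHLEGGVDGIGLFGSDIRASVRRMKQMIRRFGSDGEGEVQGKDNGALTGNSYAGGYVPWRQIIAEARKPQHQVEAISVLKKFNIQMPLAKFESVFQQLKRPDLKNFFPATHNARKVYAILRIIDDVLTWCQTLIMFEPRQDDWMHGRFLLPKVGGRAPPSEKAYMFKHRKAIFLFFRLKAVYNVGYQSFRSGLHTNITLDVFVIAFEILHRLHDTFEWGVDGETGDPHSADRLQFLVFFVPALAVTGIENEVEFNQVCRKKRRAGRKVSRRTASDAERVGDADTKMPISEDPSMGRFLHGFQFPLVIEGLSHQEQRVLGLEGNRGIVPTTWQIRDTVQLLDYSKNSGGRDARDARGVIGAATKKPKSVIIDSEGMKAELKGAVEAIFGQLQKFQKRNIYKGLDGTRKPGMSKEGWTAALGDIGCEIGDIGNTAQTGKLLRPFSIAAIGSSSKLPLPILPDFSGTVTDLNMRHHLGQLRERPIKVPIFERGAPGCLVGTASNHEGHHGASGYIGPMGGDSLFSRLIILIVKPGNKSKGIPTGGMVTYTVLEQQPRHEVYTVEEYLEHVWEQPVDPGKQSSSSTSVTRLKIEARVAKVTLKRPTPNLKARADDAGDRYVYADAILKNRTLKGLIILNEGAEEDLPKGRAQCNNVGPVRVADFWRQDQEAVNTTGSNRSPIARSPLNKIDKRVLLGDARIDFEAMVSFSVTASQLHFQPMNAVKDKIHGMNVALLKEGQLVNQNFFVDIQSMSYAYGTDDTMSVEATSLAIDYLKSRWWQPAGATDLYLHDDQLLLRPPNKSELVGQGPCIGLVQMLK","annotation":"nonribosomal peptide synthetase","_row":"nrps1"},{"gene_id":"sulf1","sequence":"NYVSGGLREDKMGSRSWGGREVGIAPDGLKATIHGCWSNNIGWGDISHDARGGGHEKEASPDFRLPPAANRYLMIEFAWFLHTPGQTMAKVKIEVGPARQAGTELPAGPLKPMAIDGWVAVKQQTDGTEIISGTTLDYLVCLQSYMFVNTPDATNYRLTYSGMTLDVTDAALANESNVENLKSRGEPEAFDVRKLTQNDCVLEKCKLEELQMFVRFGFTLASDVNCRALIYEENLKAELPVEIISHSSPEREMHRYSLLNCLTKVRNYVAEHGDFAKVEIQERIQVSQGVSADFCNRRGT","annotation":"hypothetical protein","_row":"sulf1"},{"gene_id":"orf1","sequence":"SLTFPAGPQEPKGPCTGRTSKGIRVTVFMLQADKVGNAGDVTVSSYLLEDRNLRFKFIDKKIIGIGGTDEIYEPRIKARLIVVLAQADDCSNSLAETASEFLTTRKSGKGVVTFCAMISKLTHGEVKLDIKPRWRMIGDAMVSALSPDAVRTTTVGFKPREERVFIPANILGELGDPTVGHAGVYIHLKPVFIGDTLDRPEWQTKKMPGSGTTSDIVRRENWDTNGISEGPTRKIEVDQSDANSEAIPEAAKTEQIDLLPPSLQFGTKLTWAKIIILQRDAQK","annotation":"hypothetical protein","_row":"orf1"}]}
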